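---
title: "Detecting remote protein homology with an SVM ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting remote protein homology with an SVM ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Remote homologs are proteins that share ancestry, structure and usually
function, but whose sequence identity has decayed below roughly 35% — the
"twilight zone" where alignment scores stop being informative. Detecting
such relationships is conventionally phrased as a SCOP superfamily
classification task: given a query sequence, decide which superfamily it
belongs to. The hold-out protocol is family-based. For each family in turn,
its members form the positive test set, the *other* families of the same
superfamily form the positive training set, and sequences from unrelated
folds supply the negatives, split between training and test. Because the
training and test positives come from different families, a classifier can
only succeed by generalizing across the superfamily — exactly the remote
homology setting.

`remhom` implements a weighted-voting ensemble of three support vector
machine classifiers, each built on a different fixed-length representation
of the protein sequence, together with the evaluation harness and a seeded
synthetic benchmark generator so the whole pipeline is testable without any
external database.

## Profile-based pseudo-sequences

Evolutionary information enters through frequency profiles: a 20 × L
column-stochastic matrix `M` whose entry `m[i, j]` is the probability of
amino acid `i` at position `j`, as estimated from an iterative
PSI-BLAST search. The package does not run PSI-BLAST; it parses the ASCII
PSSM files PSI-BLAST writes (`read_ascii_pssm()`, using the weighted
observed-percentage block, renormalized per column) or generates synthetic
profiles (`generate_profile()`). A profile is collapsed to its
*pseudo-sequence* by taking the most frequent residue in each column
(`profile_to_pseudo_sequence()`), so every sequence-based encoder below can
operate on profile information unchanged. Ties take the first residue in
the canonical order `ACDEFGHIKLMNPQRSTVWY`; positions whose percentage row
is all zero fall back to a one-hot column at the query residue.

## Three feature spaces

* **Kmer** (`kmer_encode()`): occurrence frequencies of all `20^k` windows
  of `k` neighboring residues, normalized by the number of counted windows.
  Default `k = 2` (400 dimensions). Captures composition and local
  ordering.
* **ACC** (`acc_encode()`): auto- and cross-covariances of three
  physicochemical signals — hydrophobicity `h1`, hydrophilicity `h2` and
  side-chain mass `m` — at lags `1..LAG`:
  `AC(u, lag) = Σ_i (P_u(R_i) − P̄_u)(P_u(R_{i+lag}) − P̄_u) / (L − lag)`,
  with the cross term `CC(u1, u2, lag)` mixing two indices. Default
  `LAG = 14`, giving `3·3·14 = 126` dimensions, ordered lag-major then by
  ordered index pair. Captures sequence-order correlation of properties,
  independent of residue identity.
* **SC-PseAAC** (`sc_pseaac_encode()`): the 20 amino-acid frequencies
  `f_u` jointly normalized with `3λ` tiered correlation factors `τ_j`
  (tier `d` averages the products of standardized `h1`, `h2`, `m` between
  residues `d` apart, divided by `L − d`):
  `x_u = f_u / (Σf + wΣτ)` and `x_{20+j} = wτ_j / (Σf + wΣτ)`.
  Defaults `λ = 5`, `w = 0.2` (35 dimensions). `λ` must satisfy
  `λ < L − 1`.

All correlation-based lookups use index values standardized to zero mean
and unit *population* variance over the 20 amino acids
(`normalize_index()`); this makes the three indices commensurable and is
required by the SC-PseAAC definition, so we apply the same convention in
ACC. The shipped index table is the canonical AAindex-derived
hydrophobicity/hydrophilicity/side-chain-mass set used throughout the
PseAAC literature; `physchem_indices(path)` accepts a replacement TSV.

Ambiguity codes are substituted on input (B→D, Z→E, J→L, U→C, O→K);
`X` and `*` become a sentinel residue that no counted k-mer window or
correlation pair may span — the corresponding windows/pairs are simply
excluded and the denominators reduced to what was counted. This avoids
inventing physicochemical values for ambiguous residues.

## Basic classifiers and the ensemble

One C-SVM with an RBF kernel is trained per (scheme, family task) on the
task's training positives and negatives (`train_basic()`; solver:
`e1071`/libsvm). Parameters are pinned rather than tuned: `C = 1` and
`gamma = 1 / (dimension × overall feature variance)`, which adapts the
bandwidth to each feature space's scale. Raw decision values are oriented
so higher means more family-like and min-max normalized into [0, 1] by the
training-pool bounds (`normalize_scores()`), clipping outside values;
degenerate bounds map to 0.5. The normalization is monotone within the
bounds, so each classifier's ROC is unaffected; its only role is to make
the three classifiers' belief values commensurable before voting.

The ensemble (`train_ensemble()`, `ensemble_score()`) combines the three
belief values by a weighted sum, with each classifier weighted by its
average ROC score on the superfamily. On which data that ROC should be
measured is genuinely open: measuring it on the test pool leaks test labels
into the model. The default therefore estimates weights by stratified
3-fold cross-validation on the training set (`estimate_weights()`), which
approximates the intended quantity honestly; `weights_from = "oracle"`
retains the literal test-ROC variant for comparison. Weights are applied
raw, not renormalized. Superfamily assignment (`assign_superfamily()`)
takes the argmax of ensemble scores over superfamilies, breaking ties by
lexicographic superfamily id.

## Evaluation

`roc_score()` is the Mann–Whitney statistic — the fraction of
(positive, negative) pairs ranked correctly, ties counting 1/2. 1 means
perfect separation, 0.5 chance. `roc50_score()` truncates the ROC curve at
the first 50 false positives and normalizes by `n_pos × min(50, n_neg)`,
so it lies in [0, 1] and reduces to the full ROC when there are at most 50
negatives. Ties in the ROC50 ranking resolve pessimistically (negatives
first), which avoids inflating the early-retrieval metric. Family-level
results are averaged unweighted across families (`run_benchmark()`), and
`grid_search()` sweeps encoder parameters, marking infeasible grid points
as failed instead of aborting.

## The synthetic benchmark

`generate_benchmark()` emulates the structure of the SCOP superfamily
benchmark at desk scale. Defaults — chosen once as the package's study
conditions — are 6 superfamilies × 3 families × 20 sequences of length
120. Each superfamily has an ancestral sequence drawn from a natural
amino-acid background; family founders are substitution-mutated copies
(rate 0.45) and family members are further mutated copies of their founder
(rate 0.15). At these rates sibling families sit near or below the
twilight zone, so detection must come from the conserved signal, not raw
identity — the regime the method is designed for. Substitutions are i.i.d.
draws from the background; there are no indels, which fixed-length
window/correlation encoders do not require.

Conserved signal is implanted as three motifs per superfamily, alternating
between two kinds so that the feature spaces carry *partially
complementary* information:

* *literal motifs* (odd superfamilies): fixed 10-residue strings over a
  superfamily-specific residue signature, re-implanted in every family
  founder — strong, identity-based k-mer signal;
* *property templates* (even superfamilies): hydrophobic/polar patterns
  with superfamily-specific period, re-instantiated with fresh residues in
  every single sequence — almost no shared k-mer content, but a conserved
  lagged-correlation structure that ACC and SC-PseAAC can read.

Every task is guaranteed ≥ 10 positive training and ≥ 5 positive test
sequences (checked before generation), train/test sets are disjoint, and
negatives never share a superfamily with the positives. The same
configuration reproduces byte-identical FASTA and split files.

What the generator does **not** emulate: insertions/deletions, realistic
phylogenetic correlation within families, length variation, database-scale
negative sets, or PSI-BLAST's search behavior (synthetic profiles are
independent Dirichlet columns centered on the true residue, not alignment
posteriors). Passing tests on this benchmark therefore demonstrate that the
pipeline's machinery is correct and that the ensemble behaves as designed
when complementary signal exists; they do not certify performance numbers
on real SCOP data.

## Numerical choices and degenerate inputs

* Argmax ties (pseudo-sequence, superfamily assignment) break
  deterministically toward the canonical/lexicographic first element.
* A constant physicochemical index cannot be standardized and raises an
  error rather than silently producing zeros.
* The SC-PseAAC joint normalizer `Σf + wΣτ` can become non-positive for
  strongly anti-correlated sequences at large `w`; this raises a
  degenerate-encoding error.
* Sequences shorter than the window (`L < k`), the maximum lag
  (`L ≤ LAG`) or the tier bound (`λ ≥ L − 1`) are rejected with errors
  naming the offending parameter.
* SVM training and scoring are deterministic given fixed inputs; all
  stochastic steps (benchmark generation, profile sampling, CV folds) are
  driven by explicit seeds through an RNG-state-preserving wrapper.

## Problem sizes used by the test suite

The packaged tests run the full pipeline on the default benchmark (360
sequences, 18 family tasks) for five generator seeds, estimate CV weights
per task, and compare every scheme combination; encoder implementations
are checked against independent naive-loop oracles on 200 random sequences
per scheme. These sizes keep a complete run in the low minutes on a single
CPU while exercising every code path at realistic dimensionality.

## A complete run

```r
library(remhom)

bench <- generate_benchmark(synth_config(seed = 1))
bs <- benchmark_scores(bench$sequences, bench$split, seed = 1)

combine_benchmark(bs, "kmer")                      # single scheme
combine_benchmark(bs, c("kmer", "acc", "sc-pseaac"))  # full ensemble
```

## Known limitations

The three basic classifiers are trained per family task, so the package
scales linearly in the number of families; no model sharing or caching is
attempted. The `weights_from = "oracle"` mode exists only for comparison
and leaks test labels by construction. ROC50's pessimistic tie rule makes
it conservative when scores are heavily tied (e.g. after clipping).
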