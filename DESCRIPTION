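Package: remhom
Title: Protein Remote Homology Detection with an SVM Ensemble over
    Profile-Based Sequence Features
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects remote protein homology at the SCOP superfamily level
    by combining three support vector machine classifiers built on
    complementary sequence encodings: k-mer composition, auto-cross
    covariance (ACC) of physicochemical indices, and series-correlation
    pseudo amino acid composition (SC-PseAAC). Frequency profiles (e.g.
    parsed from PSI-BLAST ASCII PSSM files) are converted to pseudo-sequences
    by taking the most frequent residue per position, so sequence-based
    encoders operate on evolutionary information. Per-superfamily
    classifiers are combined by weighted voting, with weights estimated as
    cross-validated ROC scores. Includes ROC/ROC50 evaluation, a family
    hold-out benchmark harness with parameter grid search, and a seeded
    generator of synthetic superfamily benchmarks for testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
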