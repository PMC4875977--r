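# Independent naive-loop oracles used to check the vectorized encoders and
# the rank-based ROC statistics. These are deliberately written as direct
# transcriptions of the defining formulas, with no code shared with R/.

AA <- remhom::AA_ALPHABET

random_seq <- function(L, alphabet = AA) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# --- k-mer composition: enumerate every window ------------------------------
oracle_kmer <- function(seq, k) {
  L <- nchar(seq)
  nm <- AA
  if (k > 1) for (j in 2:k) nm <- as.vector(t(outer(nm, AA, paste0)))
  counts <- structure(numeric(length(nm)), names = sort(nm))
  n_win <- 0L
  if (L >= k) for (i in seq_len(L - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("X", w, fixed = TRUE)) next
    counts[w] <- counts[w] + 1
    n_win <- n_win + 1L
  }
  if (n_win > 0) counts / n_win else counts
}

# --- ACC: direct double-loop evaluation of the covariance sums --------------
oracle_acc <- function(seq, lag_max, indices) {
  ch <- strsplit(seq, "")[[1]]
  vals <- indices$normalized
  keep <- ch %in% rownames(vals)
  L <- length(ch)
  out <- numeric(0)
  for (lag in seq_len(lag_max)) {
    for (u1 in indices$names) for (u2 in indices$names) {
      pbar1 <- mean(vals[ch[keep], u1])
      pbar2 <- mean(vals[ch[keep], u2])
      s <- 0; n <- 0L
      for (i in seq_len(L - lag)) {
        if (keep[i] && keep[i + lag]) {
          s <- s + (vals[ch[i], u1] - pbar1) * (vals[ch[i + lag], u2] - pbar2)
          n <- n + 1L
        }
      }
      out <- c(out, s / n)
    }
  }
  out
}

# --- tiered correlation factors: direct nested loops ------------------------
oracle_tau <- function(seq, lambda, indices) {
  ch <- strsplit(seq, "")[[1]]
  vals <- indices$normalized
  keep <- ch %in% rownames(vals)
  L <- length(ch)
  out <- numeric(0)
  for (d in seq_len(lambda)) {
    for (u in indices$names) {
      s <- 0; n <- 0L
      for (i in seq_len(L - d)) {
        if (keep[i] && keep[i + d]) {
          s <- s + vals[ch[i], u] * vals[ch[i + d], u]
          n <- n + 1L
        }
      }
      out <- c(out, s / n)
    }
  }
  out
}

# --- SC-PseAAC: scalar implementation of the joint normalization ------------
oracle_pseaac <- function(seq, lambda, w, indices) {
  ch <- strsplit(seq, "")[[1]]
  keep <- ch %in% AA
  f <- vapply(AA, function(a) sum(ch[keep] == a), numeric(1)) / sum(keep)
  tau <- oracle_tau(seq, lambda, indices)
  denom <- sum(f) + w * sum(tau)
  unname(c(f, w * tau) / denom)
}

# --- ROC: explicit pair counting --------------------------------------------
oracle_roc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# --- ROC50: exhaustive threshold sweep (distinct scores only) ---------------
oracle_roc50 <- function(pos, neg, n_fp = 50) {
  stopifnot(!anyDuplicated(c(pos, neg)))
  fmax <- min(n_fp, length(neg))
  area <- 0
  for (t in sort(c(pos, neg), decreasing = TRUE)) {
    fp <- sum(neg >= t)
    if (t %in% neg) {              # curve steps right by one false positive
      if (fp > fmax) break
      area <- area + sum(pos >= t) # height = true positives above threshold
    }
  }
  area / (length(pos) * fmax)
}

# --- synthetic PSI-BLAST ASCII PSSM text ------------------------------------
# pcts: 20 x L integer percentages with rows in canonical alphabet order
write_fake_pssm <- function(path, residues, pcts) {
  ncbi <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  header <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("           ", paste(sprintf("%3s", c(ncbi, ncbi)), collapse = ""))
  )
  rows <- vapply(seq_along(residues), function(j) {
    lo <- sprintf("%3d", rep(0L, 20))
    pc <- sprintf("%3d", pcts[match(ncbi, AA), j])
    sprintf("%5d %s %s  %s  %4.2f %8.2f", j, residues[j],
            paste(lo, collapse = ""), paste(pc, collapse = ""), 0.30, 0.10)
  }, character(1))
  footer <- c("", "                      K         Lambda",
              "Standard Ungapped    0.1337     0.3176")
  writeLines(c(header, rows, footer), path)
  invisible(path)
}

# small separable split for harness tests: two residue-biased "families"
toy_separable_benchmark <- function() {
  set.seed(42)
  mk <- function(pool, n, L = 30)
    vapply(seq_len(n), function(i) random_seq(L, pool), character(1))
  pos <- mk(c("A", "G", "S"), 18)
  neg <- mk(c("L", "K", "E"), 18)
  seqs <- c(pos, neg)
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  pos_ids <- names(seqs)[1:18]; neg_ids <- names(seqs)[19:36]
  split <- data.frame(
    family_id = "FAM1", superfamily_id = "SF1",
    seq_id = c(pos_ids[1:12], neg_ids[1:12], pos_ids[13:18], neg_ids[13:18]),
    role = rep(c("train-pos", "train-neg", "test-pos", "test-neg"),
               c(12, 12, 6, 6)))
  list(sequences = seqs, split = split)
}
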