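# Feature encoders: k-mer composition, auto-cross covariance (ACC) and
# series-correlation pseudo amino acid composition (SC-PseAAC).
#
# All three operate on sanitized residue strings. The sentinel residue X is
# never counted: k-mer windows containing it are skipped (and removed from
# the denominator), and correlation pairs touching it are skipped (with the
# pair count reduced accordingly). On sentinel-free sequences the formulas
# below reduce exactly to their textbook definitions.

# all k-mers over the canonical alphabet, first position varying slowest
kmer_names <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(AA_ALPHABET), k),
                                  stringsAsFactors = FALSE)))
}

#' K-mer composition encoding
#'
#' Represents a protein as the occurrence frequencies of all `20^k` possible
#' k-mers (length-k windows of neighboring residues). Each entry is the
#' window count divided by the number of counted windows, so the vector sums
#' to one whenever at least one window is counted. Windows containing the
#' sentinel residue `X` are skipped and excluded from the denominator.
#'
#' @param seq Residue string (a length-one character vector, possibly named).
#' @param k Window length, a positive integer (default 2, giving a
#'   400-dimensional vector).
#' @return Named numeric vector of length `20^k`, with attributes `scheme`
#'   and `params`.
#' @examples
#' kmer_encode("ACA", k = 2)[c("AC", "CA")]   # 0.5 each
#' @export
kmer_encode <- function(seq, k = 2L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer", call. = FALSE)
  idx <- aa_ints(unname(seq))
  L <- length(idx)
  if (L < k)
    stop("sequence", if (!is.null(names(seq))) paste0(" '", names(seq), "'"),
         " too short for k = ", k, " (L = ", L, ")", call. = FALSE)
  n_win <- L - k + 1L
  # integer code of each window; windows touching a sentinel become NA
  code <- integer(n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    part <- idx[j:(j + n_win - 1L)]
    valid <- valid & !is.na(part)
    part[is.na(part)] <- 1L
    code <- code + (part - 1L) * 20L^(k - j)
  }
  counts <- tabulate(code[valid] + 1L, nbins = 20L^k)
  denom <- sum(valid)
  v <- if (denom > 0) counts / denom else counts * 0
  names(v) <- kmer_names(k)
  structure(v, scheme = "kmer", params = list(k = k))
}

# L x 3 matrix of standardized index values per residue (NA at sentinels)
.index_values <- function(seq, indices) {
  idx <- aa_ints(unname(seq))
  vals <- indices$normalized[idx, , drop = FALSE]
  rownames(vals) <- NULL
  list(ints = idx, vals = vals, L = length(idx))
}

#' Auto-cross covariance (ACC) encoding
#'
#' Transforms a protein into lagged covariances of physicochemical signal
#' sequences. For each physicochemical index `u`, the autocovariance at a
#' given lag is
#' \deqn{AC(u, lag) = \sum_{i=1}^{L-lag} (P_u(R_i) - \bar P_u)(P_u(R_{i+lag}) - \bar P_u) / (L - lag)}
#' with \eqn{\bar P_u} the mean of the index along the whole sequence; the
#' cross covariance `CC(u1, u2, lag)` replaces the second factor with a
#' different index. With `N` indices the vector has length `N * N * LAG`,
#' ordered lag-major, then by ordered index pair `(u1, u2)` (the diagonal
#' pairs are the AC terms). Index values are standardized by
#' [normalize_index()] before use so the three indices are commensurable.
#'
#' @param seq Residue string.
#' @param lag_max Maximum lag LAG (default 14; with the 3 shipped indices
#'   the dimension is 126).
#' @param indices A [physchem_indices()] set.
#' @return Named numeric vector of length `N*N*lag_max` with attributes
#'   `scheme` and `params`.
#' @export
acc_encode <- function(seq, lag_max = 14L, indices = physchem_indices()) {
  lag_max <- as.integer(lag_max)
  if (lag_max < 1L) stop("lag_max must be a positive integer", call. = FALSE)
  iv <- .index_values(seq, indices)
  L <- iv$L
  if (L <= lag_max)
    stop("sequence", if (!is.null(names(seq))) paste0(" '", names(seq), "'"),
         " too short: L = ", L, " does not allow lag ", lag_max, call. = FALSE)
  nm <- indices$names
  N <- length(nm)
  ok <- !is.na(iv$ints)
  if (!any(ok)) stop("sequence contains no canonical residues", call. = FALSE)
  means <- colMeans(iv$vals[ok, , drop = FALSE])
  dev <- sweep(iv$vals, 2, means)      # rows with sentinel stay NA
  out <- numeric(N * N * lag_max)
  labels <- character(N * N * lag_max)
  pos <- 1L
  for (lag in seq_len(lag_max)) {
    a <- dev[1:(L - lag), , drop = FALSE]
    b <- dev[(1L + lag):L, , drop = FALSE]
    pair_ok <- ok[1:(L - lag)] & ok[(1L + lag):L]
    if (!any(pair_ok))
      stop("no countable residue pairs at lag ", lag, call. = FALSE)
    m <- crossprod(a[pair_ok, , drop = FALSE],
                   b[pair_ok, , drop = FALSE]) / sum(pair_ok)
    for (u1 in seq_len(N)) for (u2 in seq_len(N)) {
      out[pos] <- m[u1, u2]
      labels[pos] <- paste0(if (u1 == u2) "AC_" else "CC_",
                            nm[u1], if (u1 != u2) paste0("_", nm[u2]),
                            "_lag", lag)
      pos <- pos + 1L
    }
  }
  names(out) <- labels
  structure(out, scheme = "acc",
            params = list(lag_max = lag_max, indices = nm))
}

#' Tiered sequence-correlation factors
#'
#' Computes the `3*lambda` series-correlation factors used by SC-PseAAC.
#' For tier `d = 1..lambda` the triple \eqn{(\tau_{3d-2}, \tau_{3d-1},
#' \tau_{3d})} is the mean over `i` of the products
#' \eqn{\hat h_1(R_i)\hat h_1(R_{i+d})}, \eqn{\hat h_2(R_i)\hat h_2(R_{i+d})}
#' and \eqn{\hat m(R_i)\hat m(R_{i+d})}, each summed over the `L - d`
#' contiguous residue pairs and divided by `L - d`. Index values are the
#' standardized hydrophobicity, hydrophilicity and mass.
#'
#' @param seq Residue string.
#' @param lambda Highest correlation tier; must satisfy `lambda < L - 1`.
#' @param indices A [physchem_indices()] set.
#' @return Numeric vector `(tau_1, ..., tau_{3*lambda})`.
#' @export
tau_factors <- function(seq, lambda, indices = physchem_indices()) {
  lambda <- as.integer(lambda)
  if (lambda < 1L) stop("lambda must be a positive integer", call. = FALSE)
  iv <- .index_values(seq, indices)
  L <- iv$L
  if (lambda >= L - 1L)
    stop("lambda must satisfy lambda < L - 1 (lambda = ", lambda,
         ", L = ", L, ")", call. = FALSE)
  ok <- !is.na(iv$ints)
  N <- length(indices$names)
  tau <- numeric(N * lambda)
  for (d in seq_len(lambda)) {
    a <- iv$vals[1:(L - d), , drop = FALSE]
    b <- iv$vals[(1L + d):L, , drop = FALSE]
    pair_ok <- ok[1:(L - d)] & ok[(1L + d):L]
    if (!any(pair_ok))
      stop("no countable residue pairs at tier ", d, call. = FALSE)
    s <- colSums(a[pair_ok, , drop = FALSE] * b[pair_ok, , drop = FALSE])
    tau[(d - 1L) * N + seq_len(N)] <- s / sum(pair_ok)
  }
  names(tau) <- paste0("tau_", rep(indices$names, lambda),
                       "_tier", rep(seq_len(lambda), each = N))
  tau
}

#' Series-correlation pseudo amino acid composition (SC-PseAAC)
#'
#' Encodes a protein as its 20 amino-acid frequencies augmented with
#' `3*lambda` tiered sequence-correlation factors, jointly normalized:
#' \deqn{x_u = f_u / (\sum_i f_i + w \sum_j \tau_j)} for the 20 composition
#' components and \deqn{x_{20+j} = w \tau_j / (\sum_i f_i + w \sum_j \tau_j)}
#' for the correlation block, with \eqn{f_u} the relative residue frequency
#' (summing to one), \eqn{\tau_j} from [tau_factors()], and `w` the weight
#' balancing composition against sequence order.
#'
#' @param seq Residue string.
#' @param lambda Highest correlation tier (default 5, dimension 35);
#'   must satisfy `lambda < L - 1`.
#' @param w Weight factor in \[0, 1\] (default 0.2).
#' @param indices A [physchem_indices()] set.
#' @return Named numeric vector of length `20 + 3*lambda` with attributes
#'   `scheme` and `params`.
#' @export
sc_pseaac_encode <- function(seq, lambda = 5L, w = 0.2,
                             indices = physchem_indices()) {
  if (w < 0 || w > 1) stop("w must lie in [0, 1]", call. = FALSE)
  idx <- aa_ints(unname(seq))
  ok <- !is.na(idx)
  if (!any(ok)) stop("sequence contains no canonical residues", call. = FALSE)
  f <- tabulate(idx[ok], nbins = 20L) / sum(ok)
  tau <- tau_factors(seq, lambda, indices)
  denom <- sum(f) + w * sum(tau)
  if (denom <= 0)
    stop("degenerate encoding: normalization denominator is ", denom,
         call. = FALSE)
  v <- c(f, w * tau) / denom
  names(v) <- c(paste0("f_", AA_ALPHABET), names(tau))
  structure(v, scheme = "sc-pseaac",
            params = list(lambda = as.integer(lambda), w = w))
}

#' Encode many sequences into a feature matrix
#'
#' Applies one encoding scheme to every sequence and stacks the results
#' into a matrix (rows = sequences, in input order).
#'
#' @param seqs Named character vector of residue strings.
#' @param scheme One of `"kmer"`, `"acc"`, `"sc-pseaac"`.
#' @param params Optional list of scheme parameters (`k`; `lag_max`;
#'   `lambda`, `w`). Missing entries use the scheme defaults.
#' @param indices A [physchem_indices()] set (ACC and SC-PseAAC only).
#' @return Numeric matrix with rownames = sequence ids.
#' @export
encode_sequences <- function(seqs, scheme = c("kmer", "acc", "sc-pseaac"),
                             params = list(), indices = physchem_indices()) {
  scheme <- match.arg(scheme)
  enc <- switch(scheme,
    "kmer" = function(s) kmer_encode(s, k = params$k %||% 2L),
    "acc"  = function(s) acc_encode(s, lag_max = params$lag_max %||% 14L,
                                    indices = indices),
    "sc-pseaac" = function(s) sc_pseaac_encode(
      s, lambda = params$lambda %||% 5L, w = params$w %||% 0.2,
      indices = indices))
  rows <- lapply(seq_along(seqs), function(i) {
    unclass(enc(structure(unname(seqs[i]), names = names(seqs)[i])))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(seqs)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature matrix as TSV
#'
#' @param features Numeric matrix from [encode_sequences()].
#' @param path Output path. First column `id`, then one column per feature.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(features, path) {
  tab <- data.frame(id = rownames(features), features, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix in SVM-light sparse format
#'
#' One line per sequence: `label index:value ...`, 1-based feature indices,
#' zeros omitted.
#'
#' @param features Numeric matrix from [encode_sequences()].
#' @param labels Numeric or integer vector of labels (e.g. +1 / -1),
#'   recycled if length one.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svmlight <- function(features, labels, path) {
  labels <- rep_len(labels, nrow(features))
  lines <- vapply(seq_len(nrow(features)), function(i) {
    nz <- which(features[i, ] != 0)
    paste(labels[i], paste0(nz, ":", format(features[i, nz], trim = TRUE,
                                            scientific = FALSE),
                            collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
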