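# ROC and ROC50 scoring.

#' ROC score (normalized area under the ROC curve)
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) score pairs in which the positive outranks the
#' negative, with ties counted as 1/2. A value of 1 indicates perfect
#' separation of positives from negatives; 0.5 indicates random separation.
#'
#' @param pos_scores,neg_scores Nonempty numeric vectors of scores for the
#'   positive and negative samples (higher = more positive-like).
#' @return ROC score in \[0, 1\].
#' @export
roc_score <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L)
    stop("roc_score requires nonempty positive and negative score lists",
         call. = FALSE)
  if (anyNA(pos_scores) || anyNA(neg_scores))
    stop("scores must not contain NA", call. = FALSE)
  r <- rank(c(pos_scores, neg_scores))  # average ranks give the 1/2 tie rule
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC50 score (ROC area up to the first 50 false positives)
#'
#' All scores are ranked in descending order, with ties resolved
#' pessimistically (negatives before positives at equal score, so tied
#' positives earn no area). The ROC curve is truncated at the 50th false
#' positive — or at all negatives when there are fewer than 50 — and the
#' area is normalized by `n_pos * min(50, n_neg)` so the score lies in
#' \[0, 1\] and reduces to the full ROC when `n_neg <= 50`.
#'
#' @param pos_scores,neg_scores Nonempty numeric score vectors.
#' @param n_fp Truncation point: number of false positives (default 50).
#' @return ROC50 score in \[0, 1\].
#' @export
roc50_score <- function(pos_scores, neg_scores, n_fp = 50L) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L)
    stop("roc50_score requires nonempty positive and negative score lists",
         call. = FALSE)
  if (anyNA(pos_scores) || anyNA(neg_scores))
    stop("scores must not contain NA", call. = FALSE)
  f_max <- min(n_fp, nn)
  s <- c(pos_scores, neg_scores)
  is_pos <- rep(c(TRUE, FALSE), c(np, nn))
  ord <- order(-s, is_pos)  # at ties, negatives (FALSE) first
  tp <- 0; fp <- 0; area <- 0
  for (i in ord) {
    if (is_pos[i]) {
      tp <- tp + 1
    } else {
      fp <- fp + 1
      area <- area + tp
      if (fp == f_max) break
    }
  }
  area / (np * f_max)
}
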