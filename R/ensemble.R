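# Weighted-voting ensemble: three basic classifiers per superfamily, each
# weighted by its (cross-validated) ROC score, combined as a weighted sum of
# normalized belief values. A query is assigned to the superfamily whose
# ensemble score is highest.

#' Estimate per-scheme voting weights by cross-validated ROC
#'
#' The ensemble weight of each basic classifier is its average ROC score on
#' the task's superfamily. To avoid scoring on test labels, the average is
#' taken over stratified k-fold cross-validation on the TRAINING set: for
#' each fold, an SVM is fit on the remaining folds and the ROC of the
#' held-out fold is computed; the weight is the mean across folds.
#' Deterministic given `seed`.
#'
#' @param task A [family_task()].
#' @param features Named list of feature matrices, one per encoding scheme
#'   (ids as rownames).
#' @param folds Number of CV folds (default 3); both classes must have at
#'   least `folds` training examples.
#' @param seed Integer seed controlling the fold shuffle.
#' @param cost,gamma SVM parameters passed to [train_basic()].
#' @return Named numeric vector of weights in \[0, 1\], one per scheme.
#' @export
estimate_weights <- function(task, features, folds = 3L, seed = 1L,
                             cost = 1, gamma = NULL) {
  stopifnot(inherits(task, "family_task"))
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be at least 2", call. = FALSE)
  np <- length(task$train_pos); nn <- length(task$train_neg)
  if (np < folds || nn < folds)
    stop("task '", task$family_id, "': need at least ", folds,
         " training examples per class for ", folds, "-fold CV (have ",
         np, " pos, ", nn, " neg)", call. = FALSE)
  assign_folds <- with_seed(seed, {
    list(pos = sample(rep_len(seq_len(folds), np)),
         neg = sample(rep_len(seq_len(folds), nn)))
  })
  fp <- assign_folds$pos; fn <- assign_folds$neg
  w <- vapply(features, function(X) {
    rocs <- vapply(seq_len(folds), function(f) {
      sub <- family_task(paste0(task$family_id, "_cv", f),
                         task$superfamily_id,
                         task$train_pos[fp != f], task$train_neg[fn != f],
                         task$test_pos, task$test_neg)
      clf <- train_basic(sub, X, cost = cost, gamma = gamma)
      roc_score(score_basic(clf, X, task$train_pos[fp == f]),
                score_basic(clf, X, task$train_neg[fn == f]))
    }, numeric(1))
    mean(rocs)
  }, numeric(1))
  names(w) <- names(features)
  w
}

#' Weighted-voting ensemble score
#'
#' Combines the basic classifiers' normalized belief values for one query
#' and one superfamily as the weighted sum `sum_i w_i * s_i`. Weights are
#' applied raw (not renormalized to sum to one).
#'
#' @param scores Numeric vector of belief values in \[0, 1\] (one per basic
#'   classifier), or a matrix with one row per query.
#' @param weights Numeric vector of voting weights, same length as the
#'   number of classifiers.
#' @return Numeric ensemble score(s).
#' @export
ensemble_score <- function(scores, weights) {
  if (is.matrix(scores)) {
    stopifnot(ncol(scores) == length(weights))
    return(drop(scores %*% weights))
  }
  stopifnot(length(scores) == length(weights))
  sum(scores * weights)
}

#' Train the weighted-voting ensemble for one superfamily task
#'
#' Fits one basic classifier per encoding scheme on the task's training set
#' and attaches voting weights: either cross-validated training ROC
#' (`weights_from = "cv"`, the default) or test-set ROC
#' (`weights_from = "oracle"`, the literal-but-label-leaking variant, kept
#' for reproducing the published behavior).
#'
#' @param task A [family_task()].
#' @param features Named list of feature matrices, one per scheme.
#' @param folds,seed Passed to [estimate_weights()] when
#'   `weights_from = "cv"`.
#' @param weights_from `"cv"` or `"oracle"`.
#' @param cost,gamma SVM parameters.
#' @return An object of class `superfamily_ensemble`: list with
#'   `superfamily_id`, `task`, `classifiers`, `weights`.
#' @export
train_ensemble <- function(task, features, folds = 3L, seed = 1L,
                           weights_from = c("cv", "oracle"),
                           cost = 1, gamma = NULL) {
  weights_from <- match.arg(weights_from)
  stopifnot(inherits(task, "family_task"))
  if (is.null(names(features)) || length(features) < 1L)
    stop("features must be a nonempty named list of matrices", call. = FALSE)
  classifiers <- lapply(features, function(X)
    train_basic(task, X, cost = cost, gamma = gamma))
  weights <- switch(weights_from,
    cv = estimate_weights(task, features, folds = folds, seed = seed,
                          cost = cost, gamma = gamma),
    oracle = vapply(names(features), function(s) {
      roc_score(score_basic(classifiers[[s]], features[[s]], task$test_pos),
                score_basic(classifiers[[s]], features[[s]], task$test_neg))
    }, numeric(1)))
  structure(list(superfamily_id = task$superfamily_id, task = task,
                 classifiers = classifiers, weights = weights),
            class = "superfamily_ensemble")
}

#' Ensemble belief scores for a set of queries
#'
#' For each query id, scores every basic classifier, min-max normalizes by
#' the classifier's training-pool bounds, and combines the normalized
#' beliefs by weighted voting.
#'
#' @param ens A [train_ensemble()] result.
#' @param features Named list of feature matrices (same schemes as at
#'   training).
#' @param ids Sequence ids to score.
#' @return Named numeric vector of ensemble scores.
#' @export
predict_ensemble <- function(ens, features, ids) {
  stopifnot(inherits(ens, "superfamily_ensemble"))
  s <- vapply(names(ens$classifiers), function(sch) {
    clf <- ens$classifiers[[sch]]
    normalize_scores(score_basic(clf, features[[sch]], ids), clf$bounds)
  }, numeric(length(ids)))
  s <- matrix(s, nrow = length(ids),
              dimnames = list(ids, names(ens$classifiers)))
  ensemble_score(s, ens$weights[colnames(s)])
}

#' Assign queries to superfamilies by maximum ensemble score
#'
#' Scores each query against every superfamily's ensemble and returns the
#' superfamily with the highest ensemble score; ties are broken by
#' lexicographic superfamily id.
#'
#' @param model Named list of [train_ensemble()] results (an ensemble model
#'   over superfamilies).
#' @param features Named list of feature matrices.
#' @param ids Sequence ids to classify.
#' @return Named character vector mapping each id to a superfamily id.
#' @export
assign_superfamily <- function(model, features, ids) {
  if (length(model) == 0L)
    stop("empty ensemble model: no superfamilies to assign", call. = FALSE)
  sf_ids <- vapply(model, `[[`, character(1), "superfamily_id")
  ord <- order(sf_ids)
  model <- model[ord]; sf_ids <- sf_ids[ord]
  scores <- vapply(model, predict_ensemble, numeric(length(ids)),
                   features = features, ids = ids)
  scores <- matrix(scores, nrow = length(ids),
                   dimnames = list(ids, sf_ids))
  out <- sf_ids[apply(scores, 1, which.max)]  # first max = lexicographic tie-break
  names(out) <- ids
  out
}
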