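# Basic classifiers: one RBF-kernel SVM per (encoding scheme, family task).
# The SVM solver is e1071::svm (libsvm); its raw decision values are
# min-max normalized per classifier so the three schemes' belief functions
# are commensurable before weighted voting.

#' Construct a family hold-out task
#'
#' One benchmark task: a held-out family whose members are the positive test
#' set, with positive training examples drawn from the other families of the
#' same superfamily and negatives from outside the fold, split between
#' training and test.
#'
#' @param family_id Held-out family identifier.
#' @param superfamily_id The family's superfamily.
#' @param train_pos,train_neg,test_pos,test_neg Pairwise-disjoint character
#'   vectors of sequence ids; `train_pos` and `train_neg` must be nonempty.
#' @return An object of class `family_task`.
#' @export
family_task <- function(family_id, superfamily_id,
                        train_pos, train_neg, test_pos, test_neg) {
  sets <- list(train_pos = train_pos, train_neg = train_neg,
               test_pos = test_pos, test_neg = test_neg)
  if (length(train_pos) == 0L || length(train_neg) == 0L)
    stop("task '", family_id, "': empty training set", call. = FALSE)
  all_ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("task '", family_id, "': train/test id sets are not disjoint",
         call. = FALSE)
  structure(c(list(family_id = family_id, superfamily_id = superfamily_id),
              sets), class = "family_task")
}

#' Build family tasks from a benchmark split table
#'
#' @param split Data frame with columns `family_id`, `superfamily_id`,
#'   `seq_id`, `role` (one of `train-pos`, `train-neg`, `test-pos`,
#'   `test-neg`). One task is built per distinct `family_id`.
#' @return Named list of [family_task()] objects.
#' @export
family_tasks <- function(split) {
  need <- c("family_id", "superfamily_id", "seq_id", "role")
  if (!all(need %in% colnames(split)))
    stop("split table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  roles <- c("train-pos", "train-neg", "test-pos", "test-neg")
  if (!all(split$role %in% roles))
    stop("unknown role value(s): ",
         paste(setdiff(unique(split$role), roles), collapse = ", "),
         call. = FALSE)
  fams <- unique(split$family_id)
  out <- lapply(fams, function(f) {
    d <- split[split$family_id == f, ]
    pick <- function(r) d$seq_id[d$role == r]
    family_task(f, d$superfamily_id[1],
                pick("train-pos"), pick("train-neg"),
                pick("test-pos"), pick("test-neg"))
  })
  names(out) <- fams
  out
}

# pinned RBF bandwidth: 1 / (dimension * overall feature variance),
# falling back to 1/dimension for constant matrices
default_gamma <- function(X) {
  v <- mean((X - mean(X))^2)
  if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
}

#' Train one basic SVM classifier for a family task
#'
#' Fits an RBF-kernel C-SVM on the task's training positives and negatives
#' and records the min/max decision values over the training pool, used
#' later to min-max normalize scores into \[0, 1\]. The decision function is
#' oriented so that higher values mean more family-like. Training is
#' deterministic given fixed inputs and parameters.
#'
#' @param task A [family_task()].
#' @param vectors Numeric feature matrix with sequence ids as rownames; all
#'   train ids must be present and share one dimension.
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF bandwidth; default `1 / (dimension * feature variance)`.
#' @param class_weights Optional named class weights (`pos`, `neg`) passed
#'   to the solver; default none.
#' @return An object of class `basic_classifier` with elements `fit`,
#'   `flip`, `bounds`, `dim`, `task`.
#' @export
train_basic <- function(task, vectors, cost = 1, gamma = NULL,
                        class_weights = NULL) {
  stopifnot(inherits(task, "family_task"))
  ids <- c(task$train_pos, task$train_neg)
  missing <- setdiff(ids, rownames(vectors))
  if (length(missing))
    stop("no feature vector for id(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  X <- vectors[ids, , drop = FALSE]
  if (anyNA(X) || any(!is.finite(X)))
    stop("feature vectors contain non-finite values", call. = FALSE)
  y <- factor(rep(c("pos", "neg"),
                  c(length(task$train_pos), length(task$train_neg))),
              levels = c("pos", "neg"))
  if (is.null(gamma)) gamma <- default_gamma(X)
  fit <- e1071::svm(x = X, y = y, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = cost,
                    class.weights = class_weights, scale = FALSE)
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")[, 1]
  # libsvm's decision sign depends on label encounter order; orient it
  flip <- if (mean(dv[y == "pos"]) >= mean(dv[y == "neg"])) 1 else -1
  dv <- dv * flip
  structure(list(fit = fit, flip = flip, bounds = range(dv),
                 dim = ncol(X), gamma = gamma, cost = cost, task = task),
            class = "basic_classifier")
}

#' Raw decision values of a basic classifier
#'
#' @param clf A [train_basic()] result.
#' @param vectors Feature matrix with ids as rownames.
#' @param ids Ids to score; must all be present in `vectors`.
#' @return Named numeric vector of raw decision values (higher = more
#'   family-like). An empty `ids` yields an empty vector.
#' @export
score_basic <- function(clf, vectors, ids) {
  stopifnot(inherits(clf, "basic_classifier"))
  if (length(ids) == 0L) return(structure(numeric(0), names = character(0)))
  missing <- setdiff(ids, rownames(vectors))
  if (length(missing))
    stop("no feature vector for id(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  X <- vectors[ids, , drop = FALSE]
  if (ncol(X) != clf$dim)
    stop("feature dimension ", ncol(X), " does not match trained dimension ",
         clf$dim, call. = FALSE)
  dv <- attr(predict(clf$fit, X, decision.values = TRUE),
             "decision.values")[, 1] * clf$flip
  names(dv) <- ids
  dv
}

#' Min-max normalize decision values into \[0, 1\]
#'
#' Scales raw decision values by the training-pool bounds recorded at fit
#' time, clipping to \[0, 1\]; degenerate bounds (max = min) map everything
#' to 0.5. Normalization is monotone, so per-classifier ROC is unchanged.
#'
#' @param raw Named numeric vector of raw decision values.
#' @param bounds Length-2 numeric `(min, max)` from the training pool.
#' @return Named numeric vector in \[0, 1\].
#' @export
normalize_scores <- function(raw, bounds) {
  stopifnot(length(bounds) == 2L)
  lo <- bounds[1]; hi <- bounds[2]
  if (hi <= lo) return(structure(rep(0.5, length(raw)), names = names(raw)))
  pmin(pmax((raw - lo) / (hi - lo), 0), 1)
}
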