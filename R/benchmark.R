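# Family hold-out benchmark harness: encode once, train per family task,
# score the task's test pool, report per-family ROC / ROC50 and unweighted
# means across families.

#' Per-task normalized scores and weights for a benchmark
#'
#' Lower-level harness used by [run_benchmark()] and by analyses that
#' compare several scheme combinations without retraining: encodes all
#' sequences once per scheme, then for every family task trains the basic
#' classifiers, estimates voting weights, and records the normalized test
#' scores of each scheme.
#'
#' @param sequences Named character vector of residue strings.
#' @param split Benchmark split table (see [family_tasks()]).
#' @param schemes Character vector of encoding schemes (subset of
#'   `c("kmer", "acc", "sc-pseaac")`).
#' @param params Named list of per-scheme parameter lists, e.g.
#'   `list(kmer = list(k = 2), acc = list(lag_max = 14))`.
#' @param folds,seed CV settings for weight estimation; each task uses a
#'   seed derived deterministically from `seed` and the task index.
#' @param indices A [physchem_indices()] set.
#' @param weights_from `"cv"` (default) or `"oracle"` (test-set ROC weights).
#' @param cost,gamma SVM parameters.
#' @return List with `schemes` and `tasks`; each task entry holds
#'   `family_id`, `superfamily_id`, `weights`, `scores` (test ids x schemes,
#'   normalized to \[0, 1\]) and `is_pos`. Tasks lacking test positives or
#'   negatives are skipped with a warning.
#' @export
benchmark_scores <- function(sequences, split,
                             schemes = c("kmer", "acc", "sc-pseaac"),
                             params = list(), folds = 3L, seed = 1L,
                             indices = physchem_indices(),
                             weights_from = c("cv", "oracle"),
                             cost = 1, gamma = NULL) {
  weights_from <- match.arg(weights_from)
  schemes <- match.arg(schemes, c("kmer", "acc", "sc-pseaac"),
                       several.ok = TRUE)
  feats <- lapply(schemes, function(s)
    encode_sequences(sequences, scheme = s, params = params[[s]] %||% list(),
                     indices = indices))
  names(feats) <- schemes
  tasks <- family_tasks(split)
  out <- vector("list", length(tasks))
  names(out) <- names(tasks)
  for (i in seq_along(tasks)) {
    task <- tasks[[i]]
    if (length(task$test_pos) == 0L || length(task$test_neg) == 0L) {
      warning("family '", task$family_id,
              "' lacks test positives or negatives; skipped", call. = FALSE)
      next
    }
    ens <- train_ensemble(task, feats, folds = folds, seed = seed + i,
                          weights_from = weights_from,
                          cost = cost, gamma = gamma)
    test_ids <- c(task$test_pos, task$test_neg)
    s <- vapply(schemes, function(sch) {
      clf <- ens$classifiers[[sch]]
      normalize_scores(score_basic(clf, feats[[sch]], test_ids), clf$bounds)
    }, numeric(length(test_ids)))
    s <- matrix(s, nrow = length(test_ids),
                dimnames = list(test_ids, schemes))
    out[[i]] <- list(family_id = task$family_id,
                     superfamily_id = task$superfamily_id,
                     weights = ens$weights, scores = s,
                     is_pos = rep(c(TRUE, FALSE),
                                  c(length(task$test_pos),
                                    length(task$test_neg))))
  }
  list(schemes = schemes, tasks = Filter(Negate(is.null), out))
}

#' Per-family ROC/ROC50 from precomputed task scores
#'
#' Combines a subset of the schemes in a [benchmark_scores()] result by
#' weighted voting (or uses the single scheme's scores directly) and
#' evaluates each family task.
#'
#' @param bs A [benchmark_scores()] result.
#' @param schemes Subset of `bs$schemes` to combine; default all.
#' @return Object of class `benchmark_result`: list with `per_family`
#'   (data frame: family, superfamily, n_pos_test, n_neg_test, roc, roc50),
#'   `mean_roc`, `mean_roc50`, `schemes`.
#' @export
combine_benchmark <- function(bs, schemes = bs$schemes) {
  stopifnot(all(schemes %in% bs$schemes))
  rows <- lapply(bs$tasks, function(tk) {
    sc <- if (length(schemes) == 1L) tk$scores[, schemes]
          else ensemble_score(tk$scores[, schemes, drop = FALSE],
                              tk$weights[schemes])
    data.frame(family = tk$family_id, superfamily = tk$superfamily_id,
               n_pos_test = sum(tk$is_pos), n_neg_test = sum(!tk$is_pos),
               roc = roc_score(sc[tk$is_pos], sc[!tk$is_pos]),
               roc50 = roc50_score(sc[tk$is_pos], sc[!tk$is_pos]))
  })
  per_family <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), superfamily = character(0),
               n_pos_test = integer(0), n_neg_test = integer(0),
               roc = numeric(0), roc50 = numeric(0))
  rownames(per_family) <- NULL
  structure(list(per_family = per_family,
                 mean_roc = mean(per_family$roc),
                 mean_roc50 = mean(per_family$roc50),
                 schemes = schemes),
            class = "benchmark_result")
}

#' Run the family hold-out benchmark
#'
#' Trains one classifier (or the weighted-voting ensemble when several
#' schemes are given) per family task, scores that family's test pool and
#' reports per-family ROC and ROC50 plus their unweighted means across
#' families. Deterministic given `seed`.
#'
#' @inheritParams benchmark_scores
#' @return A `benchmark_result` (see [combine_benchmark()]).
#' @export
run_benchmark <- function(sequences, split, schemes = "kmer",
                          params = list(), folds = 3L, seed = 1L,
                          indices = physchem_indices(),
                          weights_from = c("cv", "oracle"),
                          cost = 1, gamma = NULL) {
  bs <- benchmark_scores(sequences, split, schemes = schemes,
                         params = params, folds = folds, seed = seed,
                         indices = indices, weights_from = weights_from,
                         cost = cost, gamma = gamma)
  combine_benchmark(bs)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("Family hold-out benchmark —", paste(x$schemes, collapse = " + "),
      "\n  families:", nrow(x$per_family),
      "\n  mean ROC:  ", sprintf("%.3f", x$mean_roc),
      "\n  mean ROC50:", sprintf("%.3f", x$mean_roc50), "\n")
  invisible(x)
}

#' Grid search over encoder parameters
#'
#' Evaluates [run_benchmark()] for one scheme at every row of a parameter
#' grid. Rows whose evaluation fails (e.g. `lambda >= L - 1`) are marked
#' `failed` and the search continues. The best non-failed row by mean ROC
#' is flagged.
#'
#' @param sequences,split,folds,seed,indices As in [run_benchmark()].
#' @param scheme A single encoding scheme.
#' @param grid Nonempty data frame; columns are parameter names of the
#'   scheme (`k`; `lag_max`; `lambda`, `w`).
#' @return Data frame: the grid columns plus `mean_roc`, `mean_roc50`,
#'   `failed`, `best`.
#' @export
grid_search <- function(sequences, split, scheme, grid, folds = 3L,
                        seed = 1L, indices = physchem_indices()) {
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop("grid must be a nonempty data frame of parameter values",
         call. = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    p <- as.list(grid[r, , drop = FALSE])
    params <- list(); params[[scheme]] <- p
    tryCatch({
      b <- run_benchmark(sequences, split, schemes = scheme, params = params,
                         folds = folds, seed = seed, indices = indices)
      data.frame(mean_roc = b$mean_roc, mean_roc50 = b$mean_roc50,
                 failed = FALSE)
    }, error = function(e)
      data.frame(mean_roc = NA_real_, mean_roc50 = NA_real_, failed = TRUE))
  })
  out <- cbind(grid, do.call(rbind, res))
  out$best <- FALSE
  if (any(!out$failed))
    out$best[which.max(ifelse(out$failed, -Inf, out$mean_roc))] <- TRUE
  rownames(out) <- NULL
  out
}
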