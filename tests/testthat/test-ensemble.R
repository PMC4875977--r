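# separable features: a superfamily-specific offset makes every fold split
# cleanly; noise features carry no class signal at all
sep_features <- function(task, dim = 6, shift = 5, sd = 0.2, seed = 1) {
  ids <- unlist(task[c("train_pos", "train_neg", "test_pos", "test_neg")])
  with_seed <- getFromNamespace("with_seed", "remhom")
  with_seed(seed, {
    X <- matrix(rnorm(length(ids) * dim, sd = sd), ncol = dim)
    lab <- grepl("^p", ids)
    X[lab, 1] <- X[lab, 1] + shift
    rownames(X) <- ids
    X
  })
}

noise_features <- function(task, dim = 6, seed = 1) {
  ids <- unlist(task[c("train_pos", "train_neg", "test_pos", "test_neg")])
  with_seed <- getFromNamespace("with_seed", "remhom")
  with_seed(seed, {
    X <- matrix(rnorm(length(ids) * dim), ncol = dim)
    rownames(X) <- ids
    X
  })
}

wide_task <- function(np = 24, nn = 24) {
  family_task("F1", "SF1",
              train_pos = sprintf("p%02d", 1:np),
              train_neg = sprintf("n%02d", 1:nn),
              test_pos = sprintf("pt%02d", 1:8),
              test_neg = sprintf("nt%02d", 1:8))
}

test_that("perfect fold separation yields weight 1 and symmetry equal weights", {
  task <- wide_task()
  Xs <- sep_features(task)
  w <- estimate_weights(task, list(kmer = Xs, acc = Xs, pse = Xs),
                        folds = 3, seed = 1)
  expect_equal(unname(w), rep(1, 3))       # every fold separates perfectly
  expect_equal(w[["kmer"]], w[["acc"]])    # identical features, equal weights
})

test_that("noise features earn a chance-level weight", {
  task <- wide_task()
  ws <- vapply(1:20, function(s) {
    Xn <- noise_features(task, seed = 100 + s)
    estimate_weights(task, list(noise = Xn), folds = 3, seed = s)[[1]]
  }, numeric(1))
  expect_lt(abs(mean(ws) - 0.5), 0.1)
})

test_that("weight estimation validates fold feasibility and is seed-deterministic", {
  small <- family_task("F1", "SF1", paste0("p", 1:2), paste0("n", 1:5),
                       "pt1", "nt1")
  Xn <- noise_features(small, seed = 3)
  expect_error(estimate_weights(small, list(a = Xn), folds = 3), "3-fold")
  task <- wide_task()
  Xn <- noise_features(task, seed = 4)
  expect_identical(estimate_weights(task, list(a = Xn), folds = 3, seed = 7),
                   estimate_weights(task, list(a = Xn), folds = 3, seed = 7))
})

test_that("ensemble_score is the plain weighted sum", {
  expect_equal(ensemble_score(c(0.7, 0.2, 0.9), c(1, 0, 0)), 0.7)
  expect_equal(ensemble_score(c(1, 0, 0), c(0.9, 0.6, 0.75)), 0.9)
  w <- c(0.9, 0.6, 0.75)
  expect_equal(ensemble_score(rep(0.4, 3), w), sum(w) * 0.4)
  m <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(ensemble_score(m, w), c(0.9, 0.6))
  expect_true(ensemble_score(c(0.9, 0.5, 0.5), w) >
              ensemble_score(c(0.8, 0.5, 0.5), w))  # monotone in each input
})

test_that("queries are assigned to the highest-scoring superfamily", {
  t1 <- wide_task()
  t2 <- family_task("F2", "SF2",
                    train_pos = sprintf("n%02d", 1:24),
                    train_neg = sprintf("p%02d", 1:24),
                    test_pos = sprintf("nt%02d", 1:8),
                    test_neg = sprintf("pt%02d", 1:8))
  X <- sep_features(t1)
  feats <- list(f = X)
  e1 <- train_ensemble(t1, feats, folds = 3, seed = 1)
  e2 <- train_ensemble(t2, feats, folds = 3, seed = 1)
  model <- list(SF1 = e1, SF2 = e2)
  got <- assign_superfamily(model, feats, c("pt01", "nt01"))
  expect_identical(unname(got), c("SF1", "SF2"))
  expect_error(assign_superfamily(list(), feats, "pt01"), "empty")
  # single-superfamily model: the vacuous argmax
  expect_identical(unname(assign_superfamily(list(SF1 = e1), feats, "nt01")),
                   "SF1")
})

test_that("tied ensemble scores resolve to the lexicographically first superfamily", {
  t1 <- wide_task()
  X <- sep_features(t1)
  e1 <- train_ensemble(t1, list(f = X), folds = 3, seed = 1)
  e2 <- e1; e2$superfamily_id <- "SF0"   # identical scores, different label
  got <- assign_superfamily(list(a = e1, b = e2), list(f = X), "pt01")
  expect_identical(unname(got), "SF0")
})

test_that("degenerate voting weights reduce the ensemble to one classifier", {
  bench <- generate_benchmark(synth_config(
    n_superfamilies = 3, families_per_superfamily = 3, seqs_per_family = 6,
    seq_length = 60, seed = 2))
  bs <- benchmark_scores(bench$sequences, bench$split,
                         schemes = c("kmer", "acc"), folds = 3, seed = 2)
  for (tk in bs$tasks) {
    reduced <- ensemble_score(tk$scores, c(kmer = 1, acc = 0))
    expect_equal(roc_score(reduced[tk$is_pos], reduced[!tk$is_pos]),
                 roc_score(tk$scores[tk$is_pos, "kmer"],
                           tk$scores[!tk$is_pos, "kmer"]))
  }
})
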