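test_that("roc_score matches the pair-counting definition", {
  expect_equal(roc_score(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(roc_score(0.8, c(0.9, 0.1)), 0.5)   # 1 win of 2 pairs
  expect_equal(roc_score(c(0.5, 0.5), c(0.5)), 0.5)  # ties count 1/2
  expect_error(roc_score(numeric(0), 1), "nonempty")

  set.seed(17)
  for (i in 1:500) {
    np <- sample(1:8, 1); nn <- sample(1:8, 1)
    pos <- round(runif(np), 2); neg <- round(runif(nn), 2)  # force some ties
    expect_equal(roc_score(pos, neg), oracle_roc(pos, neg))
  }
})

test_that("roc_score agrees with an established AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:20) {
    pos <- rnorm(30, 1); neg <- rnorm(50)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = rep(c(1, 0), c(30, 50)), predictor = c(pos, neg),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_score(pos, neg), auc, tolerance = 1e-12)
  }
})

test_that("roc_score complementarity and monotone-transform invariance", {
  set.seed(23)
  for (i in 1:50) {
    pos <- runif(10); neg <- runif(15)      # continuous: no ties
    expect_equal(roc_score(pos, neg) + roc_score(neg, pos), 1)
    expect_equal(roc_score(exp(3 * pos), exp(3 * neg)), roc_score(pos, neg))
  }
})

test_that("roc50 analytic anchors and reduction to roc for small negative sets", {
  expect_equal(roc50_score(c(5, 4, 3), 2:1), 1)        # perfect separation
  expect_equal(roc50_score(1:3, 4:10), 0)              # negatives on top
  set.seed(29)
  pos <- rnorm(12); neg <- rnorm(40)                    # n_neg <= 50
  expect_equal(roc50_score(pos, neg), roc_score(pos, neg))
})

test_that("roc50 equals the exhaustive threshold-sweep oracle", {
  set.seed(7)
  pos <- rnorm(10, mean = 0.5); neg <- rnorm(60)
  expect_equal(roc50_score(pos, neg), oracle_roc50(pos, neg))
  for (i in 1:30) {
    np <- sample(3:15, 1); nn <- sample(40:90, 1)
    pos <- rnorm(np, mean = runif(1)); neg <- rnorm(nn)
    expect_equal(roc50_score(pos, neg), oracle_roc50(pos, neg))
  }
})

test_that("a trivially separable family scores ROC 1 in the benchmark", {
  toy <- toy_separable_benchmark()
  b <- run_benchmark(toy$sequences, toy$split, schemes = "kmer",
                     params = list(kmer = list(k = 1)), folds = 3, seed = 1)
  expect_equal(nrow(b$per_family), 1L)
  expect_equal(b$per_family$roc, 1)
  expect_equal(b$per_family$roc50, 1)
  expect_equal(b$mean_roc, 1)
})

test_that("families without test samples are skipped with a warning", {
  toy <- toy_separable_benchmark()
  split <- toy$split[toy$split$role != "test-pos" |
                     toy$split$family_id != "FAM1", ]
  expect_warning(
    expect_error(run_benchmark(toy$sequences, split, schemes = "kmer",
                               params = list(kmer = list(k = 1))),
                 NA),
    "skipped")
})

test_that("grid search reduces to run_benchmark, is reproducible, contains failures", {
  toy <- toy_separable_benchmark()
  g1 <- grid_search(toy$sequences, toy$split, "kmer",
                    grid = data.frame(k = 1:2), folds = 3, seed = 11)
  expect_equal(nrow(g1), 2L)
  b <- run_benchmark(toy$sequences, toy$split, schemes = "kmer",
                     params = list(kmer = list(k = 1)), folds = 3, seed = 11)
  expect_equal(g1$mean_roc[1], b$mean_roc)
  g2 <- grid_search(toy$sequences, toy$split, "kmer",
                    grid = data.frame(k = 1:2), folds = 3, seed = 11)
  expect_identical(g1, g2)
  expect_true(sum(g1$best) == 1)

  # an infeasible grid point is marked failed without aborting the search
  g3 <- grid_search(toy$sequences, toy$split, "sc-pseaac",
                    grid = data.frame(lambda = c(2, 200), w = 0.2),
                    folds = 3, seed = 11)
  expect_identical(g3$failed, c(FALSE, TRUE))
  expect_true(g3$best[1])
  expect_error(grid_search(toy$sequences, toy$split, "kmer",
                           grid = data.frame()), "nonempty")
})
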