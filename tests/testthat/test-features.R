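idx <- physchem_indices()

test_that("index standardization gives zero mean and unit population variance", {
  for (u in idx$names) {
    z <- normalize_index(idx$raw[, u])
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(mean(z^2) - 1), 1e-12)
  }
  expect_error(normalize_index(rep(3, 20)), "degenerate")
})

test_that("the index table can be overridden from TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(residue = rownames(idx$raw), idx$raw)
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  idx2 <- physchem_indices(f)
  expect_equal(idx2$normalized, idx$normalized)
})

test_that("k-mer composition matches direct window counting", {
  v <- kmer_encode("MM", k = 2)
  expect_equal(unname(v["MM"]), 1)
  expect_equal(sum(v), 1)

  v <- kmer_encode("ACA", k = 2)
  expect_equal(unname(v[c("AC", "CA")]), c(0.5, 0.5))
  expect_equal(sum(v != 0), 2)

  v <- kmer_encode("AAC", k = 1)
  expect_equal(unname(v[c("A", "C")]), c(2 / 3, 1 / 3))

  expect_error(kmer_encode("AC", k = 3), "too short")

  set.seed(21)
  for (i in 1:25) {
    k <- sample(1:2, 1)
    s <- random_seq(sample((k + 1):60, 1))
    v <- kmer_encode(s, k)
    o <- oracle_kmer(s, k)
    expect_equal(unname(v[names(o)]), unname(o), tolerance = 1e-12)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_equal(length(v), 20^k)
  }
})

test_that("sentinel residues never enter a counted window", {
  v <- kmer_encode("AXAC", k = 2)        # only window "AC" is countable
  expect_equal(unname(v["AC"]), 1)
  o <- oracle_kmer("AXAC", 2)
  expect_equal(unname(v[names(o)]), unname(o))
  expect_equal(sum(kmer_encode("XAXX", k = 2)), 0)  # no countable window
})

test_that("ACC equals the direct summation of the covariance formulas", {
  # 5-residue toy, lag 1, checked component-wise against the loop oracle
  v <- acc_encode("ACDEF", lag_max = 1, indices = idx)
  expect_equal(as.numeric(v), oracle_acc("ACDEF", 1, idx), tolerance = 1e-12)
  expect_length(acc_encode(random_seq(40), lag_max = 14, indices = idx), 126)

  set.seed(33)
  for (i in 1:20) {
    lag <- sample(1:6, 1)
    s <- random_seq(sample((lag + 2):50, 1))
    expect_equal(as.numeric(acc_encode(s, lag, idx)), oracle_acc(s, lag, idx),
                 tolerance = 1e-10)
  }
})

test_that("ACC vanishes on homopolymers and reduces CC(u,u) to AC(u)", {
  for (r in c("A", "W", "M"))
    expect_equal(max(abs(acc_encode(strrep(r, 30), 5, idx))), 0)
  v <- acc_encode("ACDEFGHIKL", lag_max = 3, indices = idx)
  # diagonal pairs carry the AC_ prefix; they ARE the u1 == u2 case
  expect_named(v[c(1, 5, 9)], c("AC_h1_lag1", "AC_h2_lag1", "AC_m_lag1"))
  expect_error(acc_encode("ACDEF", lag_max = 5, indices = idx), "lag")
})

test_that("ACC is invariant under residue renaming that preserves index values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  raw <- idx$raw
  raw["G", ] <- raw["A", ]               # make A and G physicochemical twins
  write.table(data.frame(residue = rownames(raw), raw), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  twin <- physchem_indices(f)
  set.seed(5)
  s <- random_seq(40)
  swapped <- chartr("AG", "GA", s)
  expect_equal(as.numeric(acc_encode(s, 8, twin)),
               as.numeric(acc_encode(swapped, 8, twin)), tolerance = 1e-12)
})

test_that("tau factors match the nested-loop evaluation", {
  z <- idx$normalized
  expect_equal(as.numeric(tau_factors(strrep("A", 10), 1, idx)),
               as.numeric(c(z["A", "h1"]^2, z["A", "h2"]^2, z["A", "m"]^2)))
  expect_error(tau_factors("ACDEF", 4, idx), "lambda")
  expect_equal(as.numeric(tau_factors("ACDEFG", 2, idx)),
               oracle_tau("ACDEFG", 2, idx), tolerance = 1e-12)
})

test_that("SC-PseAAC matches the scalar oracle and its analytic limits", {
  v <- sc_pseaac_encode("ACDEFGHIK", lambda = 2, w = 0.2, indices = idx)
  expect_equal(as.numeric(v), oracle_pseaac("ACDEFGHIK", 2, 0.2, idx),
               tolerance = 1e-12)
  expect_length(sc_pseaac_encode(random_seq(30), lambda = 5, indices = idx), 35)

  # w = 0: correlation block vanishes, composition block sums to one
  v0 <- sc_pseaac_encode(random_seq(25), lambda = 3, w = 0, indices = idx)
  expect_equal(unname(v0[21:29]), rep(0, 9))
  expect_equal(sum(v0[1:20]), 1, tolerance = 1e-12)

  set.seed(44)
  for (i in 1:20) {
    lam <- sample(1:5, 1)
    s <- random_seq(sample((lam + 8):60, 1))
    w <- runif(1, 0, 0.5)
    expect_equal(as.numeric(sc_pseaac_encode(s, lam, w, idx)),
                 oracle_pseaac(s, lam, w, idx), tolerance = 1e-10)
  }

  # strong anti-correlated alternation can push the joint normalizer below
  # zero at large w; that is a degenerate encoding, not a vector
  expect_error(sc_pseaac_encode(strrep("IR", 8), lambda = 1, w = 1,
                                indices = idx),
               "degenerate")
})

test_that("the SC-PseAAC composition block is proportional to 1-mer composition", {
  set.seed(55)
  for (i in 1:10) {
    s <- random_seq(sample(10:60, 1))
    lam <- sample(1:4, 1); w <- runif(1)
    v <- sc_pseaac_encode(s, lam, w, idx)
    comp <- v[1:20] / sum(v[1:20])
    expect_equal(as.numeric(comp), as.numeric(kmer_encode(s, 1)), tolerance = 1e-12)
  }
})

test_that("encode_sequences stacks per-sequence vectors with ids as rownames", {
  seqs <- c(a = "ACDEFGHIKL", b = "MNPQRSTVWY")
  m <- encode_sequences(seqs, "kmer", list(k = 1))
  expect_identical(rownames(m), c("a", "b"))
  expect_equal(m["a", ], unclass(kmer_encode(seqs["a"], 1)),
               ignore_attr = TRUE)
  m2 <- encode_sequences(seqs, "sc-pseaac", list(lambda = 2, w = 0.1),
                         indices = idx)
  expect_equal(dim(m2), c(2L, 26L))
})
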