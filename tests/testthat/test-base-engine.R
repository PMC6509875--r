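test_that("cumulative functions match hand-computed values", {
  # constant weights cancel: f1 == f0, delta = 0
  cdfs <- baseCdfs(c(0.4, 1.2, 0.1), b = c(2, 2, 2))
  expect_equal(cdfs$f1, cdfs$f0)
  expect_identical(baseScore(cdfs$f0, cdfs$f1), 0)

  cdfs <- baseCdfs(c(1, 1), b = c(1, 0))
  expect_equal(cdfs$f0, c(0.5, 1))
  expect_equal(cdfs$f1, c(1, 1))

  cdfs <- baseCdfs(c(3, 2, 1), b = c(1, 0, 0))
  expect_equal(cdfs$f0, c(0.5, 5 / 6, 1))
  expect_equal(cdfs$f1, c(1, 1, 1))
  expect_equal(baseScore(cdfs$f0, cdfs$f1), 0.5)

  # both ends reach 1 and both functions are monotone
  set.seed(14)
  for (rep in 1:20) {
    inst <- randomInstance(sample(3:40, 1))
    cdfs <- baseCdfs(inst$dDir, inst$b)
    expect_equal(cdfs$f0[length(cdfs$f0)], 1, tolerance = 1e-12)
    expect_equal(cdfs$f1[length(cdfs$f1)], 1, tolerance = 1e-12)
    expect_true(all(diff(cdfs$f0) >= -1e-12))
    expect_true(all(diff(cdfs$f1) >= -1e-12))
  }

  expect_error(baseCdfs(c(0, 0), c(1, 1)), "no differentiation")
  expect_error(baseCdfs(c(1, 2), c(0, 0)), "no weight")
})

test_that("the maximum gap can be zero when f1 trails f0", {
  expect_identical(baseScore(c(0.5, 1), c(0.5, 1)), 0)
  expect_equal(baseScore(c(0.5, 1), c(0, 1)), 0)  # max(-0.5, 0)
  expect_equal(baseScore(c(0.5, 5 / 6, 1), c(1, 1, 1)), 0.5)
})

test_that("exact permutation p-values match hand enumeration", {
  pv <- permutationPvalue(c(3, 2, 1), c(0, 1, 0), exact = TRUE)
  expect_equal(pv$delta, 1 / 6)
  expect_equal(sort(pv$nullScores), c(0, 0, 1 / 6, 1 / 6, 0.5, 0.5))
  expect_equal(pv$p, 2 / 6)

  pv <- permutationPvalue(c(3, 2, 1), c(1, 0, 0), exact = TRUE)
  expect_equal(pv$delta, 0.5)
  expect_identical(pv$p, 0)

  # constant b: observed and all permuted scores are identically 0
  pv <- permutationPvalue(c(3, 2, 1), c(2, 2, 2), exact = TRUE)
  expect_identical(pv$delta, 0)
  expect_identical(pv$p, 0)
  expect_true("constant_b" %in% pv$flags)
})

test_that("exact mode equals the brute-force enumeration oracle", {
  set.seed(5)
  for (n in 3:7) {
    for (rep in 1:3) {
      inst <- randomInstance(n)
      got <- permutationPvalue(inst$dDir, inst$b, exact = TRUE)
      want <- oracleExactP(inst$dDir, inst$b)
      expect_equal(got$delta, want$delta)
      expect_equal(got$p, want$p)
      expect_equal(sort(got$nullScores), sort(want$null))
    }
  }
})

test_that("sampled p-values converge to the exact value", {
  set.seed(6)
  inst <- randomInstance(7)
  exact <- permutationPvalue(inst$dDir, inst$b, exact = TRUE)$p
  for (K in c(1000L, 100000L)) {
    p <- permutationPvalue(inst$dDir, inst$b, K = K, seed = 123)$p
    se <- sqrt(exact * (1 - exact) / K)
    expect_lt(abs(p - exact), 3 * se + 1e-12)
  }
})

test_that("the score is scale-free in both vectors", {
  set.seed(7)
  for (rep in 1:50) {
    inst <- randomInstance(sample(3:30, 1))
    base <- oracleDelta(inst$dDir, inst$b)
    c1 <- runif(1, 0.01, 100)
    c2 <- runif(1, 0.01, 100)
    cdfs <- baseCdfs(c1 * inst$dDir, c2 * inst$b)
    expect_equal(baseScore(cdfs$f0, cdfs$f1), base, tolerance = 1e-12)
  }
})

test_that("ties: the null distribution is exchangeable under reshuffling", {
  set.seed(9)
  # tied d positions are interchangeable in the null, so the multiset of
  # permuted scores never depends on the input order
  dDir <- c(2, 2, 1, 1, 0.5)
  b <- c(3, 0, 1, 2, 0)
  ref <- sort(permutationPvalue(dDir, b, exact = TRUE)$nullScores)
  for (rep in 1:5) {
    sh <- sample(length(dDir))
    got <- permutationPvalue(dDir[sh], b[sh], exact = TRUE)
    expect_equal(sort(got$nullScores), ref)
  }
  # when tied entries carry equal weights, the observed score and hence
  # the p-value are fully order-invariant as well
  b2 <- c(3, 3, 1, 1, 0)
  ref2 <- permutationPvalue(dDir, b2, exact = TRUE)
  for (rep in 1:5) {
    sh <- sample(length(dDir))
    got <- permutationPvalue(dDir[sh], b2[sh], exact = TRUE)
    expect_equal(got$p, ref2$p)
    expect_equal(got$delta, ref2$delta)
  }
})

test_that("permutation seeding is reproducible and per-test independent", {
  set.seed(77)
  inst <- randomInstance(30)
  a <- permutationPvalue(inst$dDir, inst$b, K = 500, seed = 42)
  b2 <- permutationPvalue(inst$dDir, inst$b, K = 500, seed = 42)
  expect_identical(a$p, b2$p)
  expect_identical(a$nullScores, b2$nullScores)
  c2 <- permutationPvalue(inst$dDir, inst$b, K = 500, seed = 43)
  expect_false(identical(a$nullScores, c2$nullScores))
})

test_that("runBase tests both directions, joins genes, and flags degeneracies", {
  set.seed(10)
  genes <- paste0("g", 1:60)
  d <- rnorm(60)
  counts <- matrix(rpois(180, 1), 60, 3,
                   dimnames = list(genes, c("mA", "mB", "mC")))
  counts[, 2L] <- 2L   # constant weights
  counts[, 3L] <- 0L   # no weight anywhere
  pr <- DifferentiationProfile(c(genes, "extra1", "extra2"),
                               c(d, 1, -1))
  expect_message(
    res <- runBase(pr, BindingCountMatrix(counts), K = 200, seed = 1),
    "dropped 2")
  expect_s4_class(res, "BaseResults")
  expect_identical(nrow(res), 6L)
  expect_setequal(res$direction, c("up", "down"))
  expect_true(all(res$n_genes == 60L))
  expect_true(all(res$delta >= -1 & res$delta <= 1))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(res$flags[res$motif_id == "mB"] == "constant_b"))
  mc <- res[res$motif_id == "mC", ]
  expect_true(all(mc$flags == "zero_weight"))
  expect_true(all(mc$p_value == 1))
  expect_true(all(mc$delta == 0))
  # sorted by p within direction
  for (dir in c("up", "down"))
    expect_false(is.unsorted(res$p_value[res$direction == dir]))
  # reproducible under the same master seed, regardless of motif order
  res2 <- runBase(pr, BindingCountMatrix(counts), K = 200, seed = 1)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  expect_error(
    runBase(DifferentiationProfile("zz", 1), BindingCountMatrix(counts)),
    "no genes shared")
})

test_that("a direction with no differentiation is flagged across motifs", {
  genes <- paste0("g", 1:20)
  pr <- DifferentiationProfile(genes, abs(rnorm(20)) + 0.1)  # all up
  counts <- matrix(rpois(40, 1), 20, 2,
                   dimnames = list(genes, c("m1", "m2")))
  res <- suppressMessages(runBase(pr, BindingCountMatrix(counts),
                                  K = 100, seed = 2))
  down <- res[res$direction == "down", ]
  expect_true(all(down$flags == "no_differentiation"))
  expect_true(all(down$p_value == 1))
})

test_that("rank-based scoring is invariant under monotone transforms", {
  set.seed(12)
  genes <- paste0("g", 1:80)
  d <- abs(rnorm(80)) + 0.01   # strictly positive
  counts <- matrix(rpois(240, 2), 80, 3,
                   dimnames = list(genes, c("m1", "m2", "m3")))
  cm <- BindingCountMatrix(counts)
  r1 <- runBase(DifferentiationProfile(genes, d), cm, K = 300, seed = 3,
                rankBased = TRUE)
  r2 <- runBase(DifferentiationProfile(genes, d^3), cm, K = 300, seed = 3,
                rankBased = TRUE)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$delta, r2$delta)
  # without ranks the transform changes the scores
  r3 <- runBase(DifferentiationProfile(genes, d), cm, K = 300, seed = 3)
  r4 <- runBase(DifferentiationProfile(genes, d^3), cm, K = 300, seed = 3)
  expect_false(identical(r3$delta, r4$delta))
})

test_that("the literal-f0 option reproduces the signed-d reference curve", {
  genes <- paste0("g", 1:6)
  d <- c(3, 2, 1, -1, -2, 0.5)
  counts <- matrix(c(2L, 1L, 0L, 0L, 0L, 1L), 6, 1,
                   dimnames = list(genes, "m1"))
  res <- runBase(DifferentiationProfile(genes, d),
                 BindingCountMatrix(counts), K = 50, seed = 4,
                 literalF0 = TRUE)
  # recompute by hand for the up direction
  dUp <- pmax(d, 0)
  ord <- order(dUp, decreasing = TRUE)
  f0 <- cumsum(d[ord]) / sum(d[ord])
  f1 <- cumsum(dUp[ord] * counts[ord, 1L]) / sum(dUp[ord] * counts[ord, 1L])
  expect_equal(res$delta[res$direction == "up"], max(f1 - f0))
})

test_that("FDR adjustments are monotone and floored correctly", {
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(adjustFdr(0.2), 0.2)
  expect_identical(adjustFdr(rep(1, 5)), rep(1, 5))
  expect_identical(adjustFdr(numeric()), numeric())
  expect_error(adjustFdr(c(0.5, 1.2)), "0, 1")

  set.seed(13)
  p <- runif(40)^1.5
  q <- adjustFdr(p)
  expect_identical(q, stats::p.adjust(p, "BH"))
  expect_true(all(q >= p))
  expect_false(is.unsorted(q[order(p)]))

  qs <- adjustFdr(p, method = "storey")
  expect_true(all(qs >= p))
  expect_true(all(qs <= 1))
  expect_false(is.unsorted(qs[order(p)]))
  # Storey's pi0 < 1 here, so q-values are no larger than BH
  expect_true(all(qs <= q + 1e-12))
})
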