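nearDetPwm <- function(consensus, id = "toy") {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(consensus, "")[[1L]]
  m <- t(vapply(chars, function(ch) ifelse(bases == ch, 0.97, 0.01),
                numeric(4)))
  MotifPWM(id, m)
}

test_that("similarity score is 1 on the consensus and 0 on the anti-consensus", {
  set.seed(3)
  for (rep in 1:5) {
    L <- sample(4:12, 1)
    m <- matrix(rgamma(4 * L, 1), L, 4)
    m <- m / rowSums(m)
    pwm <- MotifPWM("r", m)
    bases <- c("A", "C", "G", "T")
    consensus <- paste(bases[apply(m, 1, which.max)], collapse = "")
    anti <- paste(bases[apply(m, 1, which.min)], collapse = "")
    expect_equal(scoreWindow(pwm, consensus), 1)
    expect_equal(scoreWindow(pwm, anti), 0)
    expect_error(scoreWindow(pwm, substr(consensus, 1, L - 1)), "length")
  }
})

test_that("windows containing N and degenerate motifs score 0", {
  pwm <- nearDetPwm("ACGT")
  expect_identical(scoreWindow(pwm, "ACNT"), 0)
  uniform <- MotifPWM("flat", matrix(0.25, 4, 4))
  expect_warning(s <- scoreWindow(uniform, "ACGT"), "degenerate")
  expect_identical(s, 0)
  # both strand scans warn; the behavioural outcome is tau = 0
  res <- suppressWarnings(countHits(uniform, "ACGTACGT", 0.5))
  expect_identical(res$tau, 0L)
})

test_that("hit counting covers both strands in deterministic order", {
  # "ACGT" is reverse-complement palindromic: 2 forward + 2 reverse hits
  pwm <- nearDetPwm("ACGT")
  res <- countHits(pwm, "ACGTACGT", threshold = 0.9, geneId = "g")
  expect_identical(res$tau, 4L)
  expect_identical(res$hits$offset, c(0L, 0L, 4L, 4L))
  expect_identical(res$hits$strand, c("+", "-", "+", "-"))
  expect_true(all(res$hits$score >= 0.9))

  # all-N sequence never matches
  expect_identical(countHits(pwm, "NNNNNNNN", 0.5)$tau, 0L)
  # sequence shorter than the motif
  expect_identical(countHits(pwm, "AC", 0.5)$tau, 0L)
  # threshold 0 accepts every window on both strands
  expect_identical(countHits(pwm, "ACGTACGTAC", 0)$tau, 2L * (10L - 4L + 1L))
})

test_that("tau is non-increasing in the threshold", {
  set.seed(11)
  for (rep in 1:4) {
    pwm <- nearDetPwm(paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                            collapse = ""))
    seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    taus <- vapply(seq(0, 1, by = 0.1),
                   function(th) countHits(pwm, seq, th)$tau, 0L)
    expect_true(all(diff(taus) <= 0L))
  }
})

test_that("scanning agrees with a first-principles window enumeration", {
  set.seed(21)
  for (rep in 1:6) {
    L <- sample(3:8, 1)
    m <- matrix(rgamma(4 * L, 1), L, 4)
    m <- m / rowSums(m)
    pwm <- MotifPWM("r", m)
    chars <- sample(c("A", "C", "G", "T", "N"), sample(10:50, 1), TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
    seq <- paste(chars, collapse = "")
    th <- runif(1, 0.4, 0.95)
    expect_identical(countHits(pwm, seq, th)$tau,
                     oracleCountHits(m, seq, th))
    # spot-check individual window scores against the oracle
    o <- sample.int(nchar(seq) - L + 1L, 1L)
    expect_equal(scoreWindow(pwm, substr(seq, o, o + L - 1L)),
                 oracleScore(m, substr(seq, o, o + L - 1L)))
  }
})

test_that("planted consensus copies are recovered and background is quiet", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  consensus <- "ACGGTTCAAG"   # non-palindromic, 10 bp
  pwm <- nearDetPwm(consensus)
  for (k in 0:2) {
    bg <- sample(bases, 1200, TRUE)
    if (k > 0) {
      at <- seq(100, by = 300, length.out = k)
      for (a in at) bg[a:(a + 9)] <- strsplit(consensus, "")[[1L]]
    }
    tau <- countHits(pwm, paste(bg, collapse = ""), 0.95)$tau
    expect_gte(tau, k)
  }
  # background false positives are rare at threshold 0.95
  fp <- vapply(1:60, function(i) {
    countHits(pwm, paste(sample(bases, 1200, TRUE), collapse = ""),
              0.95)$tau > 0L
  }, logical(1))
  expect_lt(mean(fp), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("the count matrix composes per-gene hit counts", {
  set.seed(41)
  consensus <- "ACGGTTCAAG"
  pwm <- nearDetPwm(consensus, id = "m1")
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(0:2, function(k) {
    bg <- sample(bases, 400, TRUE)
    if (k > 0)
      for (a in seq(50, by = 120, length.out = k))
        bg[a:(a + 9)] <- strsplit(consensus, "")[[1L]]
    paste(bg, collapse = "")
  })
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(c(1, 501, 1001), width = 400), strand = "+",
          gene_id = c("g0", "g1", "g2"), clipped = FALSE)
  prom <- new("PromoterRegions", ranges = gr,
              seqs = Biostrings::DNAStringSet(
                stats::setNames(unlist(seqs), c("g0", "g1", "g2"))))
  cm <- buildCountMatrix(list(pwm), prom, threshold = 0.95)
  expect_identical(unname(countsMatrix(cm)[, "m1"]), 0:2)
  # single gene x single motif equals countHits directly
  cm1 <- buildCountMatrix(pwm, prom, threshold = 0.95)
  expect_identical(countsMatrix(cm1)["g2", 1L],
                   countHits(pwm, seqs[[3L]], 0.95)$tau)
  # requested extra genes appear as zero rows
  cm2 <- buildCountMatrix(list(pwm), prom, 0.95, extraGenes = "gZ")
  expect_identical(unname(countsMatrix(cm2)["gZ", ]), 0L)
})

test_that("threshold calibration hits the requested background rate", {
  pwm <- nearDetPwm("ACGGTTCAAG")
  th <- calibrateThreshold(pwm, targetFpr = 0.01, nWindows = 20000, seed = 2)
  expect_true(th > 0 && th < 1)
  set.seed(99)
  scores <- vapply(1:4000, function(i) {
    scoreWindow(pwm, paste(sample(c("A", "C", "G", "T"), 10, TRUE),
                           collapse = ""))
  }, 0)
  # score atoms (mismatch counts) limit how precisely a quantile can sit,
  # so check the achieved rate is of the right order, not exact
  emp <- mean(scores >= th)
  expect_lt(emp, 0.05)
  expect_gt(emp, 1e-4)
})
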