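genome <- smallGenome()

# Brute-force two-sided minimum-likelihood binomial p over all outcomes
bruteBinom <- function(Tn, t, prob = 0.5, alternative = "two.sided") {
  if (t == 0) return(1)
  d <- dbinom(0:t, t, prob)
  if (alternative == "greater") sum(d[(Tn + 1):(t + 1)])
  else min(1, sum(d[d <= d[Tn + 1] * (1 + 1e-7)]))
}

test_that("a uniform track yields a point-mass randomized null", {
  # every window holds exactly c reads; all peaks span L windows, so every
  # randomized interval contains exactly c*L reads
  w <- 200L
  cPerWin <- 3L
  uniGenome <- GenomeInfoDb::Seqinfo("chrA", 6e5)
  nwin <- as.integer(6e5 / w)
  pos <- rep((seq_len(nwin) - 1L) * w, each = cPerWin)  # c reads per window
  rc <- makeCenters(list(chrA = pos), uniGenome)
  Lwin <- 5L
  pk <- GRanges("chrA", IRanges(start = c(1, 2001), width = Lwin * w))
  null <- buildRandomizedNull(pk, rc, P = 1e4, seed = 5)
  expect_equal(sum(null@freq), null@total)
  counts <- which(null@freq > 0) - 1L
  expect_equal(counts, cPerWin * Lwin)  # point mass at c*L

  # p-values at and above the point mass
  expect_equal(oneSamplePValue(cPerWin * Lwin, null), 1)
  expect_equal(oneSamplePValue(cPerWin * Lwin + 1L, null), 1 / (1e4 + 1))
  expect_equal(oneSamplePValue(0L, null), 1)
})

test_that("the randomized null is reproducible and total-conserving", {
  set.seed(1)
  rc <- makeCenters(list(chrA = sort(sample(0:(6e5 - 1), 3000)),
                         chrB = sort(sample(0:(4e5 - 1), 1500))), genome)
  pk <- GRanges(c("chrA", "chrA", "chrB"),
                IRanges(start = c(1, 5001, 101), width = c(800, 1200, 400)))
  n1 <- buildRandomizedNull(pk, rc, P = 2e4, seed = 11)
  n2 <- buildRandomizedNull(pk, rc, P = 2e4, seed = 11)
  expect_identical(n1@freq, n2@freq)
  expect_equal(sum(n1@freq), 2e4)
  expect_equal(n1@tailGE[1], 2e4)
  expect_true(all(diff(n1@tailGE) <= 0))

  # monotone non-increasing in r
  p <- oneSamplePValue(0:30, n1)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("exact binomial p-values match enumeration on key cases", {
  # modal outcome: p = 1
  expect_equal(binomialTwoSample(5, 5, 1e6, 1e6)$pValue, 1)
  # 10 vs 0: one-sided 2^-10, two-sided doubled
  expect_equal(binomialTwoSample(10, 0, 1e6, 1e6,
                                 alternative = "greater")$pValue, 2^-10)
  expect_equal(binomialTwoSample(10, 0, 1e6, 1e6)$pValue, 2 * 2^-10)
  # 8 vs 2: 56/1024 one-sided, 112/1024 two-sided
  expect_equal(binomialTwoSample(8, 2, 1e6, 1e6,
                                 alternative = "greater")$pValue, 56 / 1024)
  expect_equal(binomialTwoSample(8, 2, 1e6, 1e6)$pValue, 112 / 1024)
  # swapping test and control leaves the two-sided p unchanged
  expect_equal(binomialTwoSample(7, 3, 1e6, 1e6)$pValue,
               binomialTwoSample(3, 7, 1e6, 1e6)$pValue)
  # zero trials
  expect_equal(binomialTwoSample(0, 0, 1e6, 1e6)$pValue, 1)
  expect_error(binomialTwoSample(-1, 2, 1e6, 1e6), ">= 0")
})

test_that("normalization scales counts to per-million before testing", {
  out <- binomialTwoSample(30, 30, 2e6, 1e6)
  expect_equal(out$testNorm, 15)
  expect_equal(out$controlNorm, 30)
  expect_lt(out$pValue, 1)

  # raw mode uses the library-ratio null success probability
  raw <- binomialTwoSample(30, 30, 2e6, 1e6, normalize = FALSE)
  expect_equal(raw$pValue, bruteBinom(30, 60, 2 / 3))
})

test_that("BH q-values reproduce the step-up procedure", {
  expect_equal(bhFDR(0.03), 0.03)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhFDR(c(0.5, 0)), "0, 1")

  # reference: hand step-up on shuffled input
  set.seed(9)
  p <- runif(200)^2
  q <- bhFDR(p)
  o <- order(p)
  qs <- rev(cummin(rev(length(p) * p[o] / seq_along(p))))
  expect_equal(q[o], pmin(qs, 1))
})

test_that("control-swap merging unions overlapping survivors", {
  fwd <- GRanges("chrA", IRanges(start = c(101, 2001), end = c(500, 2400)),
                 qValue = c(0.01, 0.2), direction = "up")
  rev_ <- GRanges("chrA", IRanges(start = 401, end = 800),
                  qValue = 0.004, direction = "down")
  out <- swapMerge(fwd, rev_, alpha = 0.05)
  expect_length(out, 1L)
  expect_equal(start(out), 101L)
  expect_equal(end(out), 800L)
  expect_equal(mcols(out)$direction, "down,up")
  expect_equal(mcols(out)$qValue, 0.004)

  # forward-only survivors pass through unchanged
  only <- swapMerge(fwd, rev_[0], alpha = 0.05)
  expect_equal(start(only), 101L)
  expect_equal(mcols(only)$direction, "up")

  # nothing survives the filter
  none <- swapMerge(fwd[2], rev_[0], alpha = 0.05)
  expect_length(none, 0L)
})
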