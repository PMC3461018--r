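genome <- smallGenome()

# Minimal CWTResult/ScaleThresholds pair built by hand for rule tests
madeCWT <- function(power, coef, scales, wavelet = morletWavelet()) {
  new("CWTResult", coefficients = coef, power = power,
      scales = scales, wavelet = wavelet, nSignal = ncol(power))
}
madeThr <- function(cut, scales, wavelet = morletWavelet()) {
  new("ScaleThresholds", thresholds = cut, scales = scales,
      wavelet = wavelet, pThres = 0.2, nSamples = 100L,
      sampleLength = 128L, samples = matrix(0, 0, 0), seed = NA_integer_)
}

test_that("window significance follows the threshold-and-sign rule", {
  sc <- c(4, 8)
  pow <- rbind(c(0, 2, 0, 0), c(0, 0, 3, 3))
  coef <- rbind(c(0, 1.4, 0, 0), c(0, 0, 1.7, -1.7))
  cw <- madeCWT(pow, coef, sc)
  thr <- madeThr(c(1, 1), sc)

  expect_equal(significantWindows(cw, thr), c(FALSE, TRUE, TRUE, FALSE))
  # troughs admitted when the sign gate is off
  expect_equal(significantWindows(cw, thr, requirePositive = FALSE),
               c(FALSE, TRUE, TRUE, TRUE))
  # all-zero power: nothing significant
  cw0 <- madeCWT(matrix(0, 2, 4), matrix(0, 2, 4), sc)
  expect_false(any(significantWindows(cw0, thr)))
  # scale band restriction
  expect_equal(significantWindows(cw, thr, scaleBand = c(4, 4)),
               c(FALSE, TRUE, FALSE, FALSE))
  # mismatched grids refuse to combine
  thrBad <- madeThr(c(1, 1), c(2, 4))
  expect_error(significantWindows(cw, thrBad), "different wavelet or scale")
})

test_that("gap merging aggregates runs separated by at most g windows", {
  w <- 200L
  # significant windows 3,4 and 7 (1-based): gap of 2 -> one peak at g=2
  sig <- rep(FALSE, 12)
  sig[c(3, 4, 7)] <- TRUE
  pk <- mergeWindows(sig, g = 2L, w, "chrA", 600000L)
  expect_length(pk, 1L)
  expect_equal(start(pk), (3 - 1) * w + 1)
  expect_equal(end(pk), 7 * w)

  # gap of 4 -> two peaks at g=2
  sig2 <- rep(FALSE, 12)
  sig2[c(3, 4, 9)] <- TRUE
  expect_length(mergeWindows(sig2, 2L, w, "chrA", 600000L), 2L)

  # adjacent windows merge even at g=0
  sig3 <- rep(FALSE, 6)
  sig3[c(1, 2)] <- TRUE
  pk3 <- mergeWindows(sig3, 0L, w, "chrA", 600000L)
  expect_length(pk3, 1L)
  expect_equal(width(pk3), 2L * w)

  # last window truncated at the chromosome end
  sig4 <- c(rep(FALSE, 4), TRUE)
  pk4 <- mergeWindows(sig4, 0L, w, "chrA", 950L)
  expect_equal(end(pk4), 950L)
})

test_that("read counting over peaks is half-open and conservative", {
  pk <- GRanges("chrA", IRanges(start = 1, end = 400))  # 0-based [0,400)
  rc <- makeCenters(list(chrA = c(0, 399, 400)), genome)
  expect_equal(mcols(attachReadCounts(pk, rc))$readCount, 2L)

  expect_equal(mcols(attachReadCounts(pk, makeCenters(list(), genome)))$readCount, 0L)

  pk2 <- GRanges("chrA", IRanges(start = c(1, 801), end = c(400, 1200)))
  r2 <- mcols(attachReadCounts(pk2, rc))$readCount
  expect_lte(sum(r2), librarySize(rc))
})

test_that("peak calls respect gap monotonicity and structural invariants", {
  fx <- quickPunctateSim(seed = 3)
  pre <- wavecall:::preprocessReads(fx$reads, fx$genome, 95L, 200L, FALSE)
  scales <- defaultScales(512)
  thr <- mcThresholds(pre$track, scales, pThres = 0.2, nSamples = 300L,
                      sampleLength = 512L, seed = 6, verbose = FALSE)
  res <- lapply(c(0L, 2L, 5L, 10L), function(g) {
    callPutativePeaks(pre$track, thr, pre$centers, g = g,
                      scaleBand = c(4, 10))
  })
  n <- vapply(res, length, integer(1))
  bp <- vapply(res, function(x) sum(width(x)), numeric(1))
  expect_true(all(diff(n) <= 0))   # peak count non-increasing in g
  expect_true(all(diff(bp) >= 0))  # peak bp non-decreasing in g

  pk <- res[[1]]
  expect_false(is.unsorted(pk))
  expect_true(all(width(pk) > 0))
  ov <- findOverlaps(pk, drop.self = TRUE)
  expect_length(ov, 0L)  # disjoint

  # every significant window lies inside exactly one peak
  chr <- "chrA"
  cw <- cwt(chromCounts(pre$track, chr), scales)
  sig <- significantWindows(cw, thr, scaleBand = c(4, 10))
  win <- which(sig)
  gr <- GRanges(chr, IRanges(start = (win - 1L) * 200L + 1L, width = 200L))
  expect_true(all(countOverlaps(gr, pk[seqnames(pk) == chr]) == 1L))
})

test_that("gap-scan coverage is monotone and saturates correctly", {
  fx <- quickPunctateSim(seed = 13)
  pre <- wavecall:::preprocessReads(fx$reads, fx$genome, 95L, 200L, FALSE)
  thr <- mcThresholds(pre$track, defaultScales(512), pThres = 0.2,
                      nSamples = 300L, sampleLength = 512L, seed = 6,
                      verbose = FALSE)
  tab <- gapSaturation(pre$track, thr, pre$centers, gList = c(0, 2, 5, 10),
                       topN = 200L, scaleBand = c(4, 10))
  expect_true(all(diff(tab$coverage) >= 0))
  expect_true(all(tab$coverage >= 0 & tab$coverage <= 1))

  # topN >= number of peaks: coverage equals the total in-peak fraction
  tabAll <- gapSaturation(pre$track, thr, pre$centers, gList = 0L,
                          topN = 1e6L, scaleBand = c(4, 10))
  pk <- callPutativePeaks(pre$track, thr, pre$centers, g = 0L,
                          scaleBand = c(4, 10))
  expect_equal(tabAll$coverage,
               sum(mcols(pk)$readCount) / librarySize(pre$centers))

  # a single contiguous enriched block leaves nothing to merge
  blockCounts <- list(chrA = c(numeric(200), rep(30, 20), numeric(292)))
  trB <- makeTrack(blockCounts, librarySize = 600L)
  ctrB <- makeCenters(list(chrA = rep(200 * 200L + 2000L, 600)),
                      GenomeInfoDb::Seqinfo("chrA", 512 * 200))
  thrB <- mcThresholds(trB, defaultScales(512), pThres = 0.2,
                       nSamples = 300L, sampleLength = 512L, seed = 6,
                       verbose = FALSE)
  tabB <- gapSaturation(trB, thrB, ctrB, gList = c(0, 5, 10), topN = 5L,
                        scaleBand = c(4, 10))
  expect_true(all(tabB$coverage == tabB$coverage[1]))
})
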