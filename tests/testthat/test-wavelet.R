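# Direct O(n^2) circular convolution with the time-sampled mother wavelet;
# independent of the FFT path (tests both the transform machinery and the
# analytic frequency-domain wavelet forms against the time-domain
# definitions). Scales must be >= ~4 windows so the sampled wavelet is not
# aliased.
directCWT <- function(signal, scale, wavelet) {
  n <- length(signal)
  npad <- wavecall:::nextPow2(n)
  x <- c(signal, numeric(npad - n))
  d <- seq(-npad / 2, npad / 2 - 1)
  psi <- Conj(wavecall:::waveletTimeDomain(wavelet, d / scale)) / sqrt(scale)
  vapply(seq_len(n), function(t) {
    idx <- ((t - 1 + d) %% npad) + 1L
    sum(x[idx] * psi)
  }, complex(1))
}

test_that("wavelet Fourier forms have the analytic-signal and symmetry properties", {
  omega <- seq(-pi, pi, length.out = 101)
  mor <- waveletFourierBasis(morletWavelet(), 8, omega)
  expect_true(all(mor[omega <= 0] == 0))
  expect_true(all(Im(mor) == 0))

  mh <- waveletFourierBasis(mexicanHatWavelet(), 8, omega)
  expect_equal(mh, rev(mh))            # even
  expect_true(all(Im(mh) == 0))        # real
  # admissibility: both spectra vanish at frequency zero
  expect_equal(Mod(waveletFourierBasis(mexicanHatWavelet(), 8, 0)), 0)
  expect_equal(Mod(waveletFourierBasis(morletWavelet(), 8, 0)), 0)
})

test_that("constant signals have (numerically) zero power at all scales", {
  # power-of-two length: no zero-padding, so the signal really is constant
  # (the zero-mean wavelet then nulls it exactly); with padding, the pad
  # edge is a genuine step and only the DC response vanishes
  res <- cwt(rep(5, 256), scales = c(2, 4, 8, 16))
  expect_lt(max(powerSpectrum(res)), 1e-18)
})

test_that("power scales quadratically and is invariant to sign flips", {
  set.seed(42)
  x <- rpois(256, 2)
  p1 <- powerSpectrum(cwt(x, scales = c(4, 8)))
  p3 <- powerSpectrum(cwt(3 * x, scales = c(4, 8)))
  expect_equal(p3, 9 * p1, tolerance = 1e-12)
  pneg <- powerSpectrum(cwt(-x, scales = c(4, 8)))
  expect_equal(pneg, p1, tolerance = 1e-12)
})

test_that("an impulse yields a power profile symmetric about its position", {
  x <- numeric(256)
  k <- 129L  # 1-based; center of the (unpadded) power-of-two signal
  x[k] <- 1
  p <- powerSpectrum(cwt(x, scales = c(4, 8)))
  for (j in 1:2) {
    off <- 1:60
    expect_equal(p[j, k + off], p[j, k - off], tolerance = 1e-10)
  }
})

test_that("FFT-based transform matches direct time-domain convolution", {
  set.seed(7)
  for (n in c(256L, 200L)) {
    x <- rpois(n, 1.5) + 0.3 * sin(seq_len(n) / 9)
    for (wv in list(morletWavelet(), mexicanHatWavelet())) {
      scales <- c(4, 8, 16)
      res <- cwt(x, scales = scales, wavelet = wv)
      coi <- coiMask(res)
      for (j in seq_along(scales)) {
        W <- directCWT(x, scales[j], wv)
        ok <- !coi[j, ]
        # unit-energy normalization: frequency form carries sqrt(2*pi*s),
        # the sampled time form sqrt(1/s); ratio is sqrt(2*pi*s)/... both
        # follow the same convention, so values agree directly
        scaleRef <- max(Mod(W))
        expect_lt(max(abs(Re(W)[ok] - waveletCoefficients(res)[j, ok])) /
                    scaleRef, 1e-6)
        expect_lt(max(abs(Mod(W)[ok]^2 - powerSpectrum(res)[j, ok])) /
                    scaleRef^2, 1e-6)
      }
    }
  }
})

test_that("cosine period maps to the closed-form Fourier-period scale", {
  n <- 512L
  lambda <- 32
  x <- cos(2 * pi * seq_len(n) / lambda)
  scales <- defaultScales(n)
  for (wv in list(morletWavelet(), mexicanHatWavelet())) {
    res <- cwt(x, scales = scales, wavelet = wv)
    coi <- coiMask(res)
    avg <- vapply(seq_along(scales), function(j) {
      mean(powerSpectrum(res)[j, !coi[j, ]])
    }, numeric(1))
    sStar <- lambda / (fourierPeriod(wv, 1))  # scale whose period is lambda
    sHat <- scales[which.max(avg)]
    expect_lt(abs(log2(sHat / sStar)), 0.25 + 1e-9)  # within one grid step
  }
})

test_that("circularly shifting a power-of-two signal shifts the power columns", {
  set.seed(11)
  n <- 256L
  x <- rpois(n, 2)
  k <- 37L
  xs <- c(x[(k + 1):n], x[1:k])  # shift left by k
  p1 <- powerSpectrum(cwt(x, scales = c(4, 8)))
  p2 <- powerSpectrum(cwt(xs, scales = c(4, 8)))
  expect_equal(p2, p1[, c((k + 1):n, 1:k)], tolerance = 1e-10)
})

test_that("argmax scale under Gaussian bumps grows with bump width", {
  n <- 1024L
  scales <- defaultScales(n)
  argmaxScale <- function(h) {
    x <- exp(-((seq_len(n) - n / 2)^2) / (2 * h^2))
    res <- cwt(x, scales = scales)
    scales[which.max(powerSpectrum(res)[, n / 2])]
  }
  s <- vapply(c(2, 4, 8, 16, 32), argmaxScale, numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("batched midpoint transform equals the full CWT's midpoint column", {
  set.seed(5)
  L <- 256L
  seg <- matrix(rpois(L * 5L, 1), L, 5L)
  scales <- defaultScales(L)
  for (wv in list(morletWavelet(), mexicanHatWavelet())) {
    mp <- wavecall:::midpointCWT(seg, scales, wv)
    for (i in 1:5) {
      res <- cwt(seg[, i], scales = scales, wavelet = wv)
      expect_equal(mp$power[, i], powerSpectrum(res)[, L / 2 + 1L],
                   tolerance = 1e-10)
      expect_equal(mp$coef[, i], waveletCoefficients(res)[, L / 2 + 1L],
                   tolerance = 1e-10)
    }
  }
})

test_that("degenerate signals are rejected", {
  expect_error(cwt(5), "length")
  expect_error(cwt(c(1, NA, 2, 4)), "finite")
  expect_error(cwt(1:100, scales = c(4, 2)), "increasing")
})
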