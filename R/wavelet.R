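# Continuous wavelet transform of window-count signals.
#
# The transform is computed in the frequency domain: the signal is
# zero-padded to the next power of two, FFT'd, multiplied by the conjugate
# Fourier transform of the scaled mother wavelet (unit-energy normalized by
# sqrt(2*pi*s/dt)), and inverse-FFT'd per scale. The step is one window
# (dt = 1), so scales are in window units.

#' Fourier transform of a scaled mother wavelet
#'
#' Returns the normalized Fourier transform of the scaled, conjugated mother
#' wavelet at the given angular frequencies, including the
#' `sqrt(2*pi*scale/dt)` unit-energy factor that makes power comparable
#' across scales. The Morlet spectrum is zero for non-positive frequencies
#' (analytic wavelet); the Mexican hat spectrum is real and even. Both vanish
#' at frequency zero (zero mean / admissibility).
#'
#' @param wavelet A [Wavelet-class].
#' @param scale Scale in window units (> 0).
#' @param omega Angular frequencies in radians per window (signed).
#' @param dt Sampling step (windows); fixed at 1 in the pipeline.
#' @return Complex vector of the same length as `omega`.
#' @export
waveletFourierBasis <- function(wavelet, scale, omega, dt = 1) {
  stopifnot(scale > 0)
  norm <- sqrt(2 * pi * scale / dt)
  if (wavelet@kind == "morlet") {
    base <- pi^(-0.25) * exp(-((scale * omega - wavelet@omega0)^2) / 2)
    as.complex(norm * base * (omega > 0))
  } else {
    # DOG m = 2: psi0_hat(x) = -(i^2)/sqrt(gamma(2.5)) * x^2 * exp(-x^2/2)
    x <- scale * omega
    as.complex(norm * x^2 * exp(-x^2 / 2) / sqrt(gamma(2.5)))
  }
}

# Time-domain mother wavelet psi0(eta) (unit-energy form). Used by the
# direct-convolution oracle in the test suite, not by the pipeline.
waveletTimeDomain <- function(wavelet, eta) {
  if (wavelet@kind == "morlet") {
    pi^(-0.25) * exp(1i * wavelet@omega0 * eta) * exp(-eta^2 / 2)
  } else {
    (1 - eta^2) * exp(-eta^2 / 2) / sqrt(gamma(2.5))
  }
}

#' Equivalent Fourier period of a scale
#'
#' Converts between wavelet scale and the period of the oscillation the
#' wavelet responds to most strongly: `lambda = 4*pi*s / (omega0 +
#' sqrt(2 + omega0^2))` for Morlet (about 1.03 s at omega0 = 6) and
#' `lambda = 2*pi*s / sqrt(2.5)` for the Mexican hat.
#'
#' @param wavelet A [Wavelet-class].
#' @param scale Scale(s) in window units.
#' @return Fourier period(s) in window units.
#' @export
fourierPeriod <- function(wavelet, scale) {
  if (wavelet@kind == "morlet")
    4 * pi * scale / (wavelet@omega0 + sqrt(2 + wavelet@omega0^2))
  else
    2 * pi * scale / sqrt(2.5)
}

#' Default dyadic scale grid
#'
#' Scales `s_j = s0 * 2^(j*dj)`, `j = 0..J-1`, where `J` is the smallest
#' integer such that the largest scale reaches `min(maxScale, n/4)` windows.
#' The defaults (`s0 = 2`, `dj = 0.25`, `maxScale = 1024`) cover features
#' from ~400 bp to ~200 kb at 200 bp windows.
#'
#' @param n Signal length in windows that the grid must respect.
#' @param s0 Smallest scale (windows, >= 1).
#' @param dj Scale step exponent.
#' @param maxScale Cap on the largest scale (windows).
#' @return Numeric vector of strictly increasing scales.
#' @export
defaultScales <- function(n, s0 = 2, dj = 0.25, maxScale = 1024) {
  stopifnot(s0 >= 1, dj > 0, n >= 4 * s0)
  target <- min(maxScale, n / 4)
  J <- 1L
  while (s0 * 2^((J - 1) * dj) < target) J <- J + 1L
  s0 * 2^((seq_len(J) - 1) * dj)
}

# Angular frequency grid of an n-point DFT (radians per sample, signed).
angularFrequencies <- function(n, dt = 1) {
  k <- 0:(n - 1)
  omega <- 2 * pi * k / (n * dt)
  omega[k > n / 2] <- omega[k > n / 2] - 2 * pi / dt
  omega
}

#' Continuous wavelet transform of a count signal
#'
#' Computes wavelet coefficients on a scales-by-windows grid via FFT
#' convolution with zero-padding to the next power of two (padding trimmed
#' afterwards). Stores the real part of the coefficients (used for
#' peak-versus-trough sign filtering) and the power (squared modulus).
#'
#' @param signal Numeric vector of window counts (length >= 2, finite).
#' @param scales Scale grid in window units; default [defaultScales()].
#' @param wavelet A [Wavelet-class]; default Morlet with omega0 = 6.
#' @return A [CWTResult-class].
#' @export
cwt <- function(signal, scales = defaultScales(length(signal)),
                wavelet = morletWavelet()) {
  signal <- as.numeric(signal)
  if (length(signal) < 2L) stop("signal must have length >= 2")
  if (!all(is.finite(signal))) stop("signal must be finite (no NA/NaN)")
  if (is.unsorted(scales, strictly = TRUE) || any(scales <= 0))
    stop("scales must be positive and strictly increasing")
  n <- length(signal)
  npad <- nextPow2(n)
  fx <- stats::fft(c(signal, numeric(npad - n)))
  omega <- angularFrequencies(npad)
  J <- length(scales)
  coef <- matrix(0, J, n)
  pow <- matrix(0, J, n)
  for (j in seq_len(J)) {
    wft <- Conj(waveletFourierBasis(wavelet, scales[j], omega))
    W <- stats::fft(fx * wft, inverse = TRUE)[seq_len(n)] / npad
    coef[j, ] <- Re(W)
    pow[j, ] <- Re(W)^2 + Im(W)^2
  }
  new("CWTResult", coefficients = coef, power = pow,
      scales = as.numeric(scales), wavelet = wavelet, nSignal = n)
}

#' Cone-of-influence mask
#'
#' Flags positions within the e-folding distance `sqrt(2)*s` of either end of
#' the signal, where zero-padding contaminates the coefficients. Peaks in
#' this region are retained by the caller but flagged.
#'
#' @param x A [CWTResult-class].
#' @return Logical J x T matrix; `TRUE` where edge effects matter.
#' @export
coiMask <- function(x) {
  n <- x@nSignal
  d <- pmin(seq_len(n) - 1L, n - seq_len(n))  # distance to nearest end
  outer(sqrt(2) * x@scales, d, function(ef, dd) dd < ef)
}

#' Dump a power spectrum as a dense text matrix
#'
#' Writes the scales-by-windows power matrix as TSV with a scales header
#' column, for external plotting of the position-scale energy landscape.
#'
#' @param x A [CWTResult-class].
#' @param path Output path.
#' @export
writePowerMatrix <- function(x, path) {
  tab <- cbind(scale = x@scales, as.data.frame(x@power))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Midpoint-column CWT of many equal-length segments, batched.
#
# For threshold estimation only the power-spectrum column at each segment's
# midpoint is needed; computing the single inverse-DFT sample directly
# (one FFT per segment via mvfft, then per-scale dot products) is
# algebraically identical to running cwt() on each segment and taking
# column L/2 (0-based), and avoids J full inverse FFTs per segment.
# Returns list(power = J x N, coef = J x N real parts).
midpointCWT <- function(segmat, scales, wavelet) {
  L <- nrow(segmat)
  if (nextPow2(L) != L) stop("segment length must be a power of two")
  N <- ncol(segmat)
  mid <- L %/% 2L  # 0-based midpoint index
  fx <- stats::mvfft(segmat)
  omega <- angularFrequencies(L)
  phase <- exp(2i * pi * (0:(L - 1)) * mid / L)
  WV <- vapply(scales, function(s) {
    Conj(waveletFourierBasis(wavelet, s, omega)) * phase / L
  }, complex(L))
  W <- t(crossprod(fx, WV))  # J x N complex
  list(power = Re(W)^2 + Im(W)^2, coef = Re(W))
}
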