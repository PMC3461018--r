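# Monte Carlo estimation of per-scale wavelet-power significance thresholds.
#
# N random contiguous segments of L windows are drawn from the track itself;
# each is wavelet-transformed and the power-spectrum column at the segment
# midpoint (maximally distant from the pad edges) sampled. The per-scale
# threshold is the empirical upper p_thres-quantile of the N midpoint
# powers. Because the thresholds are learned from the same track they are
# applied to, the significant-window set is invariant to any global
# rescaling of the counts.

#' Draw random track segments for threshold estimation
#'
#' Draws `nSamples` contiguous runs of `sampleLength` windows, with
#' replacement. The chromosome of each segment is chosen with probability
#' proportional to its number of eligible start windows; chromosomes with
#' fewer than `sampleLength` windows are excluded (with a message).
#'
#' @param track A [WindowTrack-class].
#' @param sampleLength Segment length in windows; must be a power of two
#'   (default `2^12`).
#' @param nSamples Number of segments N (default 5000, >= 100).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param chromosomes Optional subset of chromosomes to sample from.
#' @param verbose Log exclusions.
#' @return `sampleLength` x `nSamples` numeric matrix of counts.
#' @export
drawSegments <- function(track, sampleLength = 4096L, nSamples = 5000L,
                         seed = NULL, chromosomes = NULL, verbose = TRUE) {
  L <- as.integer(sampleLength)
  if (nextPow2(L) != L) stop("sampleLength must be a power of two")
  if (nSamples < 100L) stop("need at least 100 Monte Carlo samples")
  counts <- track@counts
  if (!is.null(chromosomes)) counts <- counts[chromosomes]
  nwin <- lengths(counts)
  eligible <- nwin >= L
  if (!any(eligible))
    stop("no chromosome has >= ", L, " windows; reduce sampleLength")
  if (any(!eligible))
    vmsg(verbose, "excluding %d chromosome(s) shorter than %d windows",
         sum(!eligible), L)
  counts <- counts[eligible]
  nstarts <- lengths(counts) - L + 1L
  withSeed(seed, {
    chr <- sample.int(length(counts), nSamples, replace = TRUE,
                      prob = nstarts)
    start <- floor(stats::runif(nSamples) * nstarts[chr]) + 1L
    seg <- matrix(0, L, nSamples)
    for (i in seq_len(nSamples))
      seg[, i] <- counts[[chr[i]]][start[i]:(start[i] + L - 1L)]
    seg
  })
}

#' Estimate per-scale power thresholds from segments
#'
#' For each segment the wavelet power at the segment midpoint is computed;
#' for each scale the threshold is the `ceiling((1 - pThres) * N)`-th order
#' statistic (ascending) of the N midpoint powers, i.e. the empirical upper
#' `pThres`-quantile. Raising `pThres` never raises a threshold.
#'
#' @param segments Matrix from [drawSegments()] (L x N).
#' @param scales Scale grid (window units).
#' @param wavelet A [Wavelet-class].
#' @param pThres Upper tail probability in (0, 1); default 0.2.
#' @param seed Seed recorded for provenance (not used here).
#' @return A [ScaleThresholds-class] carrying the sampled midpoint powers.
#' @export
estimateThresholds <- function(segments, scales, wavelet, pThres = 0.2,
                               seed = NA_integer_) {
  if (ncol(segments) < 100L) stop("need at least 100 segments")
  if (pThres <= 0 || pThres >= 1) stop("pThres must lie in (0, 1)")
  mp <- midpointCWT(segments, scales, wavelet)
  N <- ncol(segments)
  k <- as.integer(ceiling((1 - pThres) * N))
  thr <- apply(mp$power, 1L, function(v) sort(v)[k])
  new("ScaleThresholds", thresholds = as.numeric(thr),
      scales = as.numeric(scales), wavelet = wavelet,
      pThres = pThres, nSamples = as.integer(N),
      sampleLength = nrow(segments), samples = mp$power,
      seed = as.integer(seed))
}

#' Monte Carlo thresholds from a window track
#'
#' Convenience wrapper: [drawSegments()] then [estimateThresholds()].
#' By default segments are pooled across chromosomes (chromosome chosen
#' proportional to eligible windows); pass a single chromosome via
#' `chromosomes` for per-chromosome thresholds.
#'
#' @inheritParams drawSegments
#' @inheritParams estimateThresholds
#' @return A [ScaleThresholds-class].
#' @export
mcThresholds <- function(track, scales, wavelet = morletWavelet(),
                         pThres = 0.2, nSamples = 5000L,
                         sampleLength = 4096L, seed = NULL,
                         chromosomes = NULL, verbose = TRUE) {
  seg <- drawSegments(track, sampleLength = sampleLength,
                      nSamples = nSamples, seed = seed,
                      chromosomes = chromosomes, verbose = verbose)
  estimateThresholds(seg, scales, wavelet, pThres = pThres,
                     seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Serialize thresholds to / from TSV
#'
#' Two columns (scale, threshold), for reuse and inspection.
#'
#' @param x A [ScaleThresholds-class].
#' @param path File path.
#' @export
writeThresholds <- function(x, path) {
  utils::write.table(
    data.frame(scale = x@scales, threshold = x@thresholds), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
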