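# End-to-end workflows: one-sample peak calling and two-sample
# differential analysis with control swap.

preprocessReads <- function(reads, genome, shift, windowSize, verbose) {
  if (is.character(reads)) reads <- readBed(reads, genome, verbose = verbose)
  reads <- deduplicateReads(reads, verbose = verbose)
  centers <- shiftReads(reads, shift = shift, genome = genome)
  list(centers = centers, track = binCounts(centers, windowSize = windowSize))
}

emptyScoredPeaks <- function(genome) {
  GRanges(nWindows = integer(), maxPower = numeric(), boundary = logical(),
          readCount = integer(), pValue = numeric(), qValue = numeric(),
          seqinfo = genome)
}

resolveWavelet <- function(wavelet, omega0) {
  if (is(wavelet, "Wavelet")) return(wavelet)
  switch(match.arg(wavelet, c("morlet", "mexican_hat")),
         morlet = morletWavelet(omega0),
         mexican_hat = mexicanHatWavelet())
}

defaultScaleBand <- function(wavelet, scales) {
  # The calling band is matched to the mark class each wavelet targets:
  # Morlet calls at scales 4-10 windows (features of roughly 0.8-2 kb at
  # 200 bp windows; punctate TFBS/H3K4me3), the Mexican hat at 8-64
  # windows (broad domains, ~10-50 kb). Scales outside the band still
  # contribute to the power spectrum and diagnostics, not to window
  # significance: letting very large scales trigger calls merges marginal
  # background fluctuations into enormous putative peaks whose read
  # counts dominate the length-matched null, while very small scales
  # flood the putative list with single-window shot noise.
  if (wavelet@kind == "mexican_hat") c(8, 64) else c(4, 10)
}

#' One-sample wavelet peak calling
#'
#' Full workflow without a control: deduplicate and shift reads, bin into
#' windows, learn per-scale Monte Carlo power thresholds from the track,
#' call putative peaks with the gap parameter, then score each peak's read
#' count against a randomized length-matched empirical null and apply
#' Benjamini-Hochberg FDR correction genome-wide.
#'
#' @param reads A stranded `GRanges` of aligned reads, or a path to a
#'   6-column BED file.
#' @param genome A [GenomeInfoDb::Seqinfo] (or path to a chrom.sizes file).
#' @param windowSize Window width in bp (default 200).
#' @param shift Read shift in bp from the 5' end (default 95; override for
#'   data with a different fragment length).
#' @param wavelet `"morlet"` (punctate to ~10 kb features), `"mexican_hat"`
#'   (very broad domains), or a [Wavelet-class].
#' @param omega0 Morlet non-dimensional frequency (default 6).
#' @param pThres Upper tail probability for the power thresholds
#'   (0.2 punctate, 0.4 broad).
#' @param g Gap parameter in windows (0 punctate; 2 / 5 / 10 for
#'   increasingly broad histone marks).
#' @param nSamples,sampleLength Monte Carlo sample count N (default 5000)
#'   and segment length in windows (default `2^12`).
#' @param P Randomized intervals for the empirical null (default 1e6).
#' @param scaleBand Optional `c(sMin, sMax)` calling band in window units.
#' @param requirePositive See [significantWindows()].
#' @param seed Integer seed controlling both Monte Carlo stages.
#' @param verbose Log progress.
#' @return Sorted `GRanges` of scored peaks (mcols `nWindows`, `readCount`,
#'   `maxPower`, `boundary`, `pValue`, `qValue`), with the run parameters
#'   and thresholds in `metadata()`.
#' @export
callPeaks <- function(reads, genome, windowSize = 200L, shift = 95L,
                      wavelet = c("morlet", "mexican_hat"), omega0 = 6,
                      pThres = 0.2, g = 0L, nSamples = 5000L,
                      sampleLength = 4096L, P = 1e6, scaleBand = NULL,
                      requirePositive = NULL, seed = NULL, verbose = TRUE) {
  if (is.character(genome)) genome <- readChromSizes(genome)
  wv <- resolveWavelet(wavelet, omega0)
  pre <- preprocessReads(reads, genome, shift, windowSize, verbose)
  params <- list(windowSize = windowSize, shift = shift, wavelet = wv@kind,
                 omega0 = wv@omega0, pThres = pThres, g = g,
                 nSamples = nSamples, sampleLength = sampleLength, P = P,
                 seed = seed)
  if (pre$centers@librarySize == 0L) {
    vmsg(verbose, "no reads; returning zero peaks")
    out <- emptyScoredPeaks(genome)
    metadata(out) <- list(params = params)
    return(out)
  }
  scales <- defaultScales(sampleLength)
  if (is.null(scaleBand)) scaleBand <- defaultScaleBand(wv, scales)
  thr <- mcThresholds(pre$track, scales, wavelet = wv, pThres = pThres,
                      nSamples = nSamples, sampleLength = sampleLength,
                      seed = seed, verbose = verbose)
  peaks <- callPutativePeaks(pre$track, thr, pre$centers, g = g,
                             scaleBand = scaleBand,
                             requirePositive = requirePositive)
  vmsg(verbose, "%d putative peaks", length(peaks))
  if (!length(peaks)) {
    out <- emptyScoredPeaks(genome)
    metadata(out) <- list(params = params, thresholds = thr)
    return(out)
  }
  null <- buildRandomizedNull(peaks, pre$centers, P = P,
                              seed = if (is.null(seed)) NULL else seed + 1L)
  mcols(peaks)$pValue <- oneSamplePValue(mcols(peaks)$readCount, null)
  mcols(peaks)$qValue <- bhFDR(mcols(peaks)$pValue)
  metadata(peaks) <- list(params = params, thresholds = thr, null = null)
  peaks
}

scoreAgainstControl <- function(peaks, centersT, centersC, alternative,
                                normalize) {
  if (!length(peaks)) return(peaks)
  cT <- mcols(attachReadCounts(peaks, centersT))$readCount
  cC <- mcols(attachReadCounts(peaks, centersC))$readCount
  bt <- binomialTwoSample(cT, cC, centersT@librarySize,
                          centersC@librarySize, alternative = alternative,
                          normalize = normalize)
  mcols(peaks)$readCount <- cT
  mcols(peaks)$controlCount <- cC
  mcols(peaks)$testNorm <- bt$testNorm
  mcols(peaks)$controlNorm <- bt$controlNorm
  mcols(peaks)$fold <- (bt$testNorm + 1) / (bt$controlNorm + 1)
  mcols(peaks)$direction <- ifelse(bt$testNorm >= bt$controlNorm,
                                   "up", "down")
  mcols(peaks)$pValue <- bt$pValue
  mcols(peaks)$qValue <- bhFDR(bt$pValue)
  peaks
}

#' Two-sample differential region calling with control swap
#'
#' Putative peaks are called on the test sample and each is tested for a
#' read-count imbalance against the control with the exact binomial test;
#' the samples are then swapped (peaks called on the control, same test) to
#' capture regions higher in the control; both FDR-filtered lists are
#' merged into a non-redundant list of differentially marked regions.
#' Direction is always relative to the first (test) sample: `"up"` = more
#' reads in test.
#'
#' @inheritParams callPeaks
#' @param controlReads Control sample (`GRanges` or BED path).
#' @param alpha FDR cutoff for the merged DMR list (default 0.05).
#' @param alternative,normalize See [binomialTwoSample()].
#' @return `GRanges` of merged DMRs (mcols `direction`, `qValue`), with the
#'   full forward and reverse scored peak sets in `metadata()`.
#' @export
diffPeaks <- function(reads, controlReads, genome, windowSize = 200L,
                      shift = 95L, wavelet = c("morlet", "mexican_hat"),
                      omega0 = 6, pThres = 0.2, g = 0L, nSamples = 5000L,
                      sampleLength = 4096L, scaleBand = NULL,
                      requirePositive = NULL, alpha = 0.05,
                      alternative = "two.sided", normalize = TRUE,
                      seed = NULL, verbose = TRUE) {
  if (is.character(genome)) genome <- readChromSizes(genome)
  wv <- resolveWavelet(wavelet, omega0)
  preT <- preprocessReads(reads, genome, shift, windowSize, verbose)
  preC <- preprocessReads(controlReads, genome, shift, windowSize, verbose)
  scales <- defaultScales(sampleLength)
  if (is.null(scaleBand)) scaleBand <- defaultScaleBand(wv, scales)
  onePass <- function(pre) {
    if (pre$centers@librarySize == 0L) return(GRanges())
    # same seed for both passes so that swapping the inputs exactly
    # reverses the analysis
    thr <- mcThresholds(pre$track, scales, wavelet = wv, pThres = pThres,
                        nSamples = nSamples, sampleLength = sampleLength,
                        seed = seed, verbose = verbose)
    callPutativePeaks(pre$track, thr, pre$centers, g = g,
                      scaleBand = scaleBand,
                      requirePositive = requirePositive)
  }
  fwd <- scoreAgainstControl(onePass(preT), preT$centers, preC$centers,
                             alternative, normalize)
  rvs <- scoreAgainstControl(onePass(preC), preT$centers, preC$centers,
                             alternative, normalize)
  dmrs <- swapMerge(fwd, rvs, alpha = alpha)
  metadata(dmrs) <- list(
    forward = fwd, reverse = rvs,
    params = list(windowSize = windowSize, shift = shift,
                  wavelet = wv@kind, pThres = pThres, g = g,
                  nSamples = nSamples, sampleLength = sampleLength,
                  alpha = alpha, alternative = alternative,
                  normalize = normalize, seed = seed))
  dmrs
}
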