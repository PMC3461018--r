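# Thresholded wavelet power -> significant windows -> putative peaks.

#' Significant windows from thresholded wavelet power
#'
#' A window is significant iff its power exceeds the per-scale threshold at
#' some scale within the calling band; with `requirePositive` the real
#' coefficient at the scale of maximal threshold excess must additionally be
#' positive, so enrichment hot spots are kept and troughs rejected.
#'
#' @param cw A [CWTResult-class] for one chromosome.
#' @param thr A [ScaleThresholds-class] computed with the same wavelet and
#'   scale grid.
#' @param scaleBand Length-2 numeric `c(sMin, sMax)` restricting the scales
#'   used for calling, or `NULL` for the full grid.
#' @param requirePositive Logical (default `TRUE`): the transform responds
#'   to enrichment hot spots (positive coefficient) and depletion troughs
#'   (negative) alike; peak calling keeps only the former.
#' @return Logical vector over windows.
#' @export
significantWindows <- function(cw, thr, scaleBand = NULL,
                               requirePositive = NULL) {
  if (!isTRUE(all.equal(cw@scales, thr@scales)) ||
      cw@wavelet@kind != thr@wavelet@kind)
    stop("thresholds were computed with a different wavelet or scale grid")
  if (is.null(requirePositive)) requirePositive <- TRUE
  band <- seq_along(cw@scales)
  if (!is.null(scaleBand)) {
    band <- which(cw@scales >= scaleBand[1L] & cw@scales <= scaleBand[2L])
    if (!length(band)) stop("scaleBand selects no scales")
  }
  excess <- cw@power[band, , drop = FALSE] - thr@thresholds[band]
  top <- max.col(t(excess), ties.method = "first")
  idx <- cbind(top, seq_len(cw@nSignal))
  sig <- excess[idx] > 0
  if (requirePositive)
    sig <- sig & (cw@coefficients[band, , drop = FALSE][idx] > 0)
  sig
}

#' Merge significant windows into putative peaks
#'
#' Maximal runs of significant windows separated by at most `g`
#' non-significant windows are aggregated into one peak; bridged gaps lie in
#' the peak interior, and peak ends always coincide with significant
#' windows (the gap never extends a peak edge into background). There is no
#' upper limit on the non-significant windows a merged peak may contain.
#'
#' @param sig Logical vector over windows (one chromosome).
#' @param g Non-negative integer gap parameter.
#' @param windowSize Window width in bp.
#' @param chrom Chromosome name.
#' @param chromLength Chromosome length in bp (truncates the last window).
#' @return A `GRanges` of peaks with mcols `nWindows` (span in windows).
#' @export
mergeWindows <- function(sig, g, windowSize, chrom, chromLength) {
  stopifnot(g >= 0)
  g <- as.integer(g)
  if (!any(sig)) return(GRanges())
  r <- rle(sig)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  sigRuns <- which(r$values)
  first <- runStart[sigRuns]
  last <- runEnd[sigRuns]
  if (length(sigRuns) > 1L) {
    gapLen <- first[-1L] - last[-length(last)] - 1L
    newPeak <- c(TRUE, gapLen > g)
  } else newPeak <- TRUE
  grp <- cumsum(newPeak)
  pf <- tapply(first, grp, min)
  pl <- tapply(last, grp, max)
  GRanges(chrom,
          IRanges(start = (pf - 1L) * windowSize + 1L,
                  end = pmin(pl * windowSize, chromLength)),
          nWindows = as.integer(pl - pf + 1L))
}

#' Count shifted read centers inside peaks
#'
#' Fills the `readCount` metadata column: the number of shifted fragment
#' centers falling in each peak interval (half-open in 0-based bp terms).
#'
#' @param peaks A `GRanges` of peaks.
#' @param centers The [ReadCenters-class] the track was built from.
#' @return `peaks` with mcols `readCount`.
#' @export
attachReadCounts <- function(peaks, centers) {
  r <- integer(length(peaks))
  chrom <- as.character(seqnames(peaks))
  for (chr in unique(chrom)) {
    p <- centers@positions[[chr]]
    i <- chrom == chr
    if (is.null(p) || !length(p)) next
    # peak [start, end] 1-based closed == 0-based [start-1, end)
    r[i] <- findInterval(end(peaks)[i] - 0.5, p) -
      findInterval(start(peaks)[i] - 1L - 0.5, p)
  }
  mcols(peaks)$readCount <- r
  peaks
}

#' Call putative peaks genome-wide
#'
#' Runs the CWT per chromosome on the raw count track, thresholds the power
#' spectrum, merges significant windows with the gap parameter, and attaches
#' read counts, maximal in-band power, and a cone-of-influence boundary
#' flag.
#'
#' @param track Raw [WindowTrack-class].
#' @param thr [ScaleThresholds-class] for the track.
#' @param centers [ReadCenters-class] used to build the track.
#' @param g Gap parameter (windows); 0 for punctate marks, 2 for
#'   H3K4me3-like, 5 for H3K36me3-like, 10 for H3K27me3-like data.
#' @param scaleBand,requirePositive See [significantWindows()].
#' @return Sorted `GRanges` with mcols `nWindows`, `readCount`, `maxPower`,
#'   `boundary`.
#' @export
callPutativePeaks <- function(track, thr, centers, g = 0L,
                              scaleBand = NULL, requirePositive = NULL) {
  if (track@normalized)
    stop("peak calling runs on the raw track (thresholds are self-scaled)")
  sl <- GenomeInfoDb::seqlengths(track@seqinfo)
  out <- list()
  for (chr in names(track@counts)) {
    v <- track@counts[[chr]]
    if (length(v) < 2L || !any(v > 0)) next
    cw <- cwt(v, scales = thr@scales, wavelet = thr@wavelet)
    sig <- significantWindows(cw, thr, scaleBand = scaleBand,
                              requirePositive = requirePositive)
    pk <- mergeWindows(sig, g, track@windowSize, chr, sl[[chr]])
    if (!length(pk)) next
    GenomeInfoDb::seqlevels(pk) <- GenomeInfoDb::seqnames(track@seqinfo)
    GenomeInfoDb::seqinfo(pk) <- track@seqinfo
    band <- seq_along(thr@scales)
    if (!is.null(scaleBand))
      band <- which(thr@scales >= scaleBand[1L] & thr@scales <= scaleBand[2L])
    w1 <- (start(pk) - 1L) %/% track@windowSize + 1L
    w2 <- (end(pk) - 1L) %/% track@windowSize + 1L
    mcols(pk)$maxPower <- vapply(seq_along(pk), function(i) {
      max(cw@power[band, w1[i]:w2[i]])
    }, numeric(1))
    efold <- sqrt(2) * max(thr@scales[band])
    n <- length(v)
    mcols(pk)$boundary <- (w1 - 1L) < efold | (n - w2) < efold
    out[[chr]] <- pk
  }
  if (!length(out))
    return(GRanges(nWindows = integer(), maxPower = numeric(),
                   boundary = logical(), seqinfo = track@seqinfo))
  pk <- do.call(c, unname(out))
  attachReadCounts(sort(pk), centers)
}

#' Gap-size read-coverage saturation diagnostic
#'
#' For each candidate gap size, calls peaks, ranks them by read count, and
#' reports the fraction of the library covered by the top `topN` peaks. The
#' curve saturates quickly for punctate marks and gradually for broad ones,
#' guiding the choice of `g`.
#'
#' @param track,thr,centers As in [callPutativePeaks()].
#' @param gList Integer vector of gap sizes to scan.
#' @param topN Number of top peaks to accumulate.
#' @param ... Passed to [callPutativePeaks()].
#' @return `data.frame(g, nPeaks, coverage)` with coverage non-decreasing
#'   in `g`.
#' @export
gapSaturation <- function(track, thr, centers, gList = c(0, 2, 5, 10),
                          topN = 1000L, ...) {
  stopifnot(length(gList) >= 1L)
  rows <- lapply(gList, function(g) {
    pk <- callPutativePeaks(track, thr, centers, g = g, ...)
    r <- sort(mcols(pk)$readCount, decreasing = TRUE)
    data.frame(g = g, nPeaks = length(pk),
               coverage = sum(utils::head(r, topN)) / centers@librarySize)
  })
  do.call(rbind, rows)
}
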