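#' @importFrom IRanges isDisjoint
NULL

#' @rdname ReadCenters-class
#' @param x,object An object.
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname WindowTrack-class
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname WindowTrack-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname WindowTrack-class
#' @export
setGeneric("chromCounts", function(x, chrom) standardGeneric("chromCounts"))

#' @rdname CWTResult-class
#' @export
setGeneric("scales", function(x) standardGeneric("scales"))

#' @rdname CWTResult-class
#' @export
setGeneric("powerSpectrum", function(x) standardGeneric("powerSpectrum"))

#' @rdname CWTResult-class
#' @export
setGeneric("waveletCoefficients",
           function(x) standardGeneric("waveletCoefficients"))

#' @rdname ScaleThresholds-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @export
#' @rdname ReadCenters-class
setMethod("librarySize", "ReadCenters", function(x) x@librarySize)

#' @export
#' @rdname WindowTrack-class
setMethod("librarySize", "WindowTrack", function(x) x@librarySize)

#' @export
#' @rdname WindowTrack-class
setMethod("windowSize", "WindowTrack", function(x) x@windowSize)

#' @export
#' @rdname WindowTrack-class
setMethod("isNormalized", "WindowTrack", function(x) x@normalized)

#' @export
#' @rdname WindowTrack-class
setMethod("chromCounts", "WindowTrack",
          function(x, chrom) x@counts[[chrom]])

#' @export
#' @rdname CWTResult-class
setMethod("scales", "CWTResult", function(x) x@scales)

#' @export
#' @rdname ScaleThresholds-class
setMethod("scales", "ScaleThresholds", function(x) x@scales)

#' @export
#' @rdname CWTResult-class
setMethod("powerSpectrum", "CWTResult", function(x) x@power)

#' @export
#' @rdname CWTResult-class
setMethod("waveletCoefficients", "CWTResult", function(x) x@coefficients)

#' @export
#' @rdname ScaleThresholds-class
setMethod("thresholds", "ScaleThresholds", function(x) x@thresholds)

#' @export
#' @rdname ReadCenters-class
setMethod("seqinfo", "ReadCenters", function(x) x@seqinfo)

#' @export
#' @rdname WindowTrack-class
setMethod("seqinfo", "WindowTrack", function(x) x@seqinfo)

setMethod("show", "Wavelet", function(object) {
  if (object@kind == "morlet")
    cat(sprintf("Morlet wavelet (omega0 = %g)\n", object@omega0))
  else
    cat("Mexican hat wavelet\n")
})

setMethod("show", "ReadCenters", function(object) {
  cat(sprintf("ReadCenters: %d positions on %d chromosome(s)\n",
              object@librarySize, length(object@positions)))
})

setMethod("show", "WindowTrack", function(object) {
  cat(sprintf(
    "WindowTrack: %d bp windows on %d chromosome(s), %s counts (library %d)\n",
    object@windowSize, length(object@counts),
    if (object@normalized) "per-million" else "raw", object@librarySize))
})

setMethod("show", "CWTResult", function(object) {
  cat(sprintf("CWTResult: %d scales x %d windows (%s)\n",
              length(object@scales), object@nSignal,
              object@wavelet@kind))
  cat(sprintf("  scales %g..%g windows\n",
              min(object@scales), max(object@scales)))
})

setMethod("show", "ScaleThresholds", function(object) {
  cat(sprintf(
    "ScaleThresholds: %d scales, p_thres = %g (N = %d, L = %d)\n",
    length(object@scales), object@pThres, object@nSamples,
    object@sampleLength))
})

setMethod("show", "RandomizedNull", function(object) {
  cat(sprintf(
    "RandomizedNull: P = %d randomized intervals, counts 0..%d\n",
    object@total, length(object@freq) - 1L))
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(
    "SimSpec: %d chromosome(s), background %g reads/%d bp window, %d spike(s)\n",
    length(GenomeInfoDb::seqlengths(object@seqinfo)), object@backgroundRate,
    object@windowSize, length(object@spikes)))
})
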