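#' @import methods
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo seqinfo<-
#'   seqlevels seqlevels<-
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom GenomicRanges GRanges start end width strand
#'   countOverlaps reduce
#' @importFrom stats fft mvfft runif rpois rnorm rbinom dbinom pbinom p.adjust
NULL

#' Mother wavelet specification
#'
#' A mother wavelet for the continuous wavelet transform. Two families are
#' supported: the Morlet wavelet (a complex plane wave under a Gaussian
#' envelope, parameterised by the non-dimensional frequency `omega0`) and the
#' Mexican hat (the negative second derivative of a Gaussian; no free
#' parameter). Morlet responds well to punctate and moderately broad
#' enrichment; the Mexican hat has a flatter energy distribution across
#' scales and suits very broad, diffuse domains.
#'
#' @slot kind Character, `"morlet"` or `"mexican_hat"`.
#' @slot omega0 Numeric, non-dimensional frequency (Morlet only). Must be at
#'   least 5 so that the wavelet is numerically admissible (zero mean).
#' @export
setClass("Wavelet", representation(kind = "character", omega0 = "numeric"))

setValidity("Wavelet", function(object) {
  msg <- NULL
  if (!object@kind %in% c("morlet", "mexican_hat"))
    msg <- c(msg, "kind must be 'morlet' or 'mexican_hat'")
  if (object@kind == "morlet" &&
      (length(object@omega0) != 1L || !is.finite(object@omega0) ||
       object@omega0 < 5))
    msg <- c(msg, "Morlet omega0 must be a single number >= 5 (admissibility)")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn Wavelet Morlet wavelet constructor.
#' @param omega0 Non-dimensional frequency; default 6 (the standard
#'   admissible choice).
#' @export
morletWavelet <- function(omega0 = 6) {
  new("Wavelet", kind = "morlet", omega0 = as.numeric(omega0))
}

#' @describeIn Wavelet Mexican hat wavelet constructor.
#' @export
mexicanHatWavelet <- function() {
  new("Wavelet", kind = "mexican_hat", omega0 = NA_real_)
}

#' Shifted read centers
#'
#' Strand-aware genomic point events: per-chromosome sorted vectors of
#' fragment-center positions (0-based bp) obtained by shifting reads from
#' their 5' ends, plus the library size (total retained reads).
#'
#' @slot positions Named list of sorted integer vectors, one per chromosome.
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] describing the genome.
#' @slot librarySize Integer, total number of positions.
#' @export
setClass("ReadCenters", representation(
  positions = "list", seqinfo = "Seqinfo", librarySize = "integer"))

setValidity("ReadCenters", function(object) {
  msg <- NULL
  sl <- GenomeInfoDb::seqlengths(object@seqinfo)
  if (!all(names(object@positions) %in% names(sl)))
    msg <- c(msg, "positions has chromosomes absent from seqinfo")
  for (chr in names(object@positions)) {
    p <- object@positions[[chr]]
    if (is.unsorted(p)) msg <- c(msg, sprintf("positions unsorted on %s", chr))
    if (length(p) && (p[1L] < 0L || p[length(p)] >= sl[[chr]]))
      msg <- c(msg, sprintf("positions out of bounds on %s", chr))
  }
  if (object@librarySize != sum(lengths(object@positions)))
    msg <- c(msg, "librarySize must equal the total number of positions")
  if (is.null(msg)) TRUE else msg
})

#' Windowed read-count track
#'
#' Per-chromosome vectors of read counts over fixed, non-overlapping windows.
#' Counts are raw integers after [binCounts()] and per-million reals after
#' [normalizePerMillion()].
#'
#' @slot counts Named list of numeric vectors, one per chromosome; length of
#'   each is `ceiling(chrom_length / windowSize)`.
#' @slot windowSize Integer window width in bp.
#' @slot librarySize Integer, reads in the originating library.
#' @slot normalized Logical; `TRUE` after per-million scaling.
#' @slot seqinfo A [GenomeInfoDb::Seqinfo].
#' @export
setClass("WindowTrack", representation(
  counts = "list", windowSize = "integer", librarySize = "integer",
  normalized = "logical", seqinfo = "Seqinfo"))

setValidity("WindowTrack", function(object) {
  msg <- NULL
  sl <- GenomeInfoDb::seqlengths(object@seqinfo)
  if (!setequal(names(object@counts), names(sl)))
    msg <- c(msg, "counts must have one vector per seqinfo chromosome")
  for (chr in names(object@counts)) {
    want <- ceiling(sl[[chr]] / object@windowSize)
    if (length(object@counts[[chr]]) != want)
      msg <- c(msg, sprintf("counts[['%s']] must have %d windows", chr, want))
    if (any(object@counts[[chr]] < 0))
      msg <- c(msg, sprintf("negative counts on %s", chr))
  }
  if (object@windowSize <= 0L) msg <- c(msg, "windowSize must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Continuous wavelet transform of one chromosome track
#'
#' Holds the real part of the wavelet coefficients and the wavelet power
#' (squared modulus) on a scales-by-windows grid, for a single chromosome
#' signal, together with the scale grid and wavelet used.
#'
#' @slot coefficients J x T numeric matrix, real part of the coefficients.
#' @slot power J x T numeric matrix, squared modulus.
#' @slot scales Numeric vector of J scales (window units), increasing.
#' @slot wavelet The [Wavelet-class] used.
#' @slot nSignal Integer, signal length T in windows.
#' @export
setClass("CWTResult", representation(
  coefficients = "matrix", power = "matrix", scales = "numeric",
  wavelet = "Wavelet", nSignal = "integer"))

setValidity("CWTResult", function(object) {
  msg <- NULL
  J <- length(object@scales)
  if (nrow(object@power) != J || nrow(object@coefficients) != J)
    msg <- c(msg, "matrices must have one row per scale")
  if (ncol(object@power) != object@nSignal)
    msg <- c(msg, "power must have one column per signal window")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (is.unsorted(object@scales, strictly = TRUE))
    msg <- c(msg, "scales must be strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' Per-scale Monte Carlo wavelet-power thresholds
#'
#' Empirical upper-quantile power cutoffs per scale, learned by transforming
#' random contiguous segments of the data track and collecting the power
#' spectrum column at each segment midpoint.
#'
#' @slot thresholds Numeric vector, one cutoff per scale.
#' @slot scales The scale grid the thresholds belong to.
#' @slot wavelet The [Wavelet-class] used.
#' @slot pThres Upper tail probability used for the cutoff.
#' @slot nSamples Number of Monte Carlo segments.
#' @slot sampleLength Segment length in windows (a power of two).
#' @slot samples J x N matrix of the sampled midpoint powers (diagnostics).
#' @slot seed Integer seed used, or NA.
#' @export
setClass("ScaleThresholds", representation(
  thresholds = "numeric", scales = "numeric", wavelet = "Wavelet",
  pThres = "numeric", nSamples = "integer", sampleLength = "integer",
  samples = "matrix", seed = "integer"))

setValidity("ScaleThresholds", function(object) {
  msg <- NULL
  if (length(object@thresholds) != length(object@scales))
    msg <- c(msg, "one threshold per scale required")
  if (any(object@thresholds < 0)) msg <- c(msg, "thresholds must be >= 0")
  if (object@pThres <= 0 || object@pThres >= 1)
    msg <- c(msg, "pThres must lie in (0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Randomized empirical null for one-sample peak significance
#'
#' Frequency distribution F(R) of shifted-read-center counts R inside P
#' intervals whose lengths are resampled from the putative-peak length
#' distribution and whose genomic positions are uniform.
#'
#' @slot freq Integer vector; `freq[i]` is the number of randomized intervals
#'   containing exactly `i - 1` reads.
#' @slot total Integer P, the number of randomized intervals.
#' @slot tailGE Numeric vector; `tailGE[i]` = number of randomized intervals
#'   with count >= `i - 1` (so `tailGE[1] == total`).
#' @slot seed Integer seed used, or NA.
#' @export
setClass("RandomizedNull", representation(
  freq = "integer", total = "integer", tailGE = "numeric", seed = "integer"))

setValidity("RandomizedNull", function(object) {
  msg <- NULL
  if (sum(object@freq) != object@total)
    msg <- c(msg, "freq must sum to total")
  if (length(object@tailGE) != length(object@freq) ||
      object@tailGE[1L] != object@total ||
      is.unsorted(rev(object@tailGE)))
    msg <- c(msg, "tailGE must be a non-increasing tail sum starting at total")
  if (is.null(msg)) TRUE else msg
})

#' Synthetic ChIP-Seq experiment specification
#'
#' Describes a simulated genome: Poisson background read placement at
#' `backgroundRate` expected reads per window, plus spiked enrichment
#' intervals with a fold increase over background, of `block` (uniform) or
#' `gaussian` (tapered, sd = width/4) shape. Fragment centers are expanded
#' into stranded reads of `readLength` bp whose 5' ends sit
#' `fragmentLength/2` bp from the center, emulating sonicated/nucleosomal
#' fragments.
#'
#' @slot seqinfo Genome definition ([GenomeInfoDb::Seqinfo]).
#' @slot backgroundRate Expected background reads per window.
#' @slot windowSize Window width (bp) that `backgroundRate` refers to.
#' @slot spikes [GenomicRanges::GRanges] with mcols `fold` (> 1) and `shape`
#'   (`"block"` or `"gaussian"`); non-overlapping, within bounds.
#' @slot fragmentLength DNA fragment length in bp (default 190,
#'   mononucleosome plus linker).
#' @slot readLength Sequenced read length in bp.
#' @export
setClass("SimSpec", representation(
  seqinfo = "Seqinfo", backgroundRate = "numeric", windowSize = "integer",
  spikes = "GRanges", fragmentLength = "integer", readLength = "integer"))

setValidity("SimSpec", function(object) {
  msg <- NULL
  sp <- object@spikes
  if (length(sp)) {
    if (is.null(sp$fold) || any(sp$fold <= 1))
      msg <- c(msg, "spike fold must be > 1")
    if (is.null(sp$shape) || !all(sp$shape %in% c("block", "gaussian")))
      msg <- c(msg, "spike shape must be 'block' or 'gaussian'")
    if (!isDisjoint(sp)) msg <- c(msg, "spikes must not overlap")
    sl <- GenomeInfoDb::seqlengths(object@seqinfo)
    if (any(end(sp) > sl[as.character(seqnames(sp))]))
      msg <- c(msg, "spikes must lie within chromosome bounds")
  }
  if (object@backgroundRate <= 0)
    msg <- c(msg, "backgroundRate must be positive")
  if (object@fragmentLength < 0L || object@readLength <= 0L)
    msg <- c(msg, "fragmentLength must be >= 0 and readLength > 0")
  if (is.null(msg)) TRUE else msg
})
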