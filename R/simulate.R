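# Synthetic ChIP-Seq experiments with known ground truth.
#
# Background fragment centers follow a homogeneous Poisson process; inside
# spiked intervals the rate is multiplied by the fold (block shape) or by a
# Gaussian-tapered fold profile (sd = width/4). Centers are expanded into
# stranded fixed-length reads whose 5' ends lie fragmentLength/2 bp from
# the center, so that shifting by fragmentLength/2 recovers the center
# exactly.

#' Construct a synthetic experiment specification
#'
#' @param genome A [GenomeInfoDb::Seqinfo], or a named vector of chromosome
#'   lengths.
#' @param backgroundRate Expected background reads per window (default 0.5).
#' @param spikes `GRanges` of enrichment intervals with mcols `fold` (> 1)
#'   and `shape` (`"block"` or `"gaussian"`); default none.
#' @param windowSize Window width in bp the rate refers to (default 200).
#' @param fragmentLength Fragment length in bp (default 190).
#' @param readLength Read length in bp (default 36).
#' @return A [SimSpec-class].
#' @export
simSpec <- function(genome, backgroundRate = 0.5, spikes = GRanges(),
                    windowSize = 200L, fragmentLength = 190L,
                    readLength = 36L) {
  if (!is(genome, "Seqinfo"))
    genome <- Seqinfo(seqnames = names(genome),
                      seqlengths = as.integer(genome))
  new("SimSpec", seqinfo = genome, backgroundRate = backgroundRate,
      windowSize = as.integer(windowSize), spikes = spikes,
      fragmentLength = as.integer(fragmentLength),
      readLength = as.integer(readLength))
}

#' Place non-overlapping spikes across a genome
#'
#' Divides the genome into `n` equal slots (proportionally across
#' chromosomes) and places one spike per slot at a random offset, which
#' guarantees non-overlap while spreading spikes genome-wide. Widths are
#' drawn uniformly from `widthRange`.
#'
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param n Number of spikes.
#' @param widthRange Length-2 bp range of spike widths.
#' @param fold Fold enrichment over background (> 1).
#' @param shape `"block"` or `"gaussian"`.
#' @param seed Optional integer seed.
#' @return `GRanges` with mcols `fold`, `shape`.
#' @export
tileSpikes <- function(genome, n, widthRange, fold, shape = "block",
                       seed = NULL) {
  sl <- GenomeInfoDb::seqlengths(genome)
  nPer <- pmax(round(n * sl / sum(sl)), 1L)
  # adjust to exactly n
  while (sum(nPer) > n) nPer[which.max(nPer)] <- nPer[which.max(nPer)] - 1L
  while (sum(nPer) < n) nPer[which.min(nPer)] <- nPer[which.min(nPer)] + 1L
  withSeed(seed, {
    out <- lapply(names(sl), function(chr) {
      k <- nPer[[chr]]
      if (k < 1L) return(GRanges())
      slot <- sl[[chr]] %/% k
      w <- round(runif(k, widthRange[1L], widthRange[2L]))
      if (any(w >= slot))
        stop("spike width does not fit the slot; reduce n or widths")
      off <- floor(runif(k) * (slot - w - 1L))
      st <- (seq_len(k) - 1L) * slot + off + 1L
      GRanges(chr, IRanges(start = st, width = w), fold = fold,
              shape = shape, seqinfo = genome)
    })
    sort(do.call(c, out[lengths(out) > 0L]))
  })
}

# Draw fragment-center positions (0-based bp) for one chromosome.
simulateCenters <- function(chr, len, spec) {
  lambdaBg <- spec@backgroundRate * len / spec@windowSize
  centers <- floor(runif(rpois(1L, lambdaBg)) * len)
  sp <- spec@spikes[seqnames(spec@spikes) == chr]
  for (i in seq_along(sp)) {
    fold <- sp$fold[i]
    w <- width(sp)[i]
    s0 <- start(sp)[i] - 1L
    perBp <- (fold - 1) * spec@backgroundRate / spec@windowSize
    if (sp$shape[i] == "block") {
      nEx <- rpois(1L, perBp * w)
      ex <- s0 + floor(runif(nEx) * w)
    } else {
      sdv <- w / 4
      mu <- s0 + w / 2
      # mass of the Gaussian profile restricted to the interval (+-2 sd)
      nEx <- rpois(1L, perBp * sdv * sqrt(2 * pi) *
                     (stats::pnorm(2) - stats::pnorm(-2)))
      ex <- round(stats::qnorm(runif(nEx, stats::pnorm(-2), stats::pnorm(2)),
                               mean = mu, sd = sdv))
      ex <- pmax(s0, pmin(ex, s0 + w - 1L))
    }
    centers <- c(centers, ex)
  }
  sort(as.integer(centers))
}

#' Simulate a ChIP-Seq read set with ground truth
#'
#' Generates Poisson background reads plus spiked enrichment as described
#' by the [SimSpec-class];
#' every fragment center becomes one read of `readLength` bp on a uniformly
#' random strand with its 5' end `fragmentLength/2` bp from the center
#' (clamped to the chromosome). Deterministic under `seed`.
#'
#' @param spec A [SimSpec-class].
#' @param seed Optional integer seed.
#' @return `list(reads = GRanges, truth = GRanges)`; `truth` carries the
#'   spike intervals with their fold and shape.
#' @export
simulateReads <- function(spec, seed = NULL) {
  sl <- GenomeInfoDb::seqlengths(spec@seqinfo)
  if (!length(sl) || any(sl <= 0)) stop("genome must have positive lengths")
  half <- spec@fragmentLength %/% 2L
  withSeed(seed, {
    parts <- lapply(names(sl), function(chr) {
      ctr <- simulateCenters(chr, sl[[chr]], spec)
      if (!length(ctr)) return(GRanges())
      plus <- runif(length(ctr)) < 0.5
      # + read: 5' end at center - half; - read: 5' end at center + half
      start0 <- ifelse(plus, ctr - half, ctr + half - spec@readLength + 1L)
      start0 <- pmax(0L, pmin(as.integer(start0),
                              sl[[chr]] - spec@readLength))
      GRanges(chr, IRanges(start = start0 + 1L, width = spec@readLength),
              strand = ifelse(plus, "+", "-"), seqinfo = spec@seqinfo)
    })
    parts <- parts[lengths(parts) > 0L]
    reads <- if (length(parts)) do.call(c, parts) else GRanges(seqinfo = spec@seqinfo)
    list(reads = reads, truth = spec@spikes)
  })
}

#' Simulate a matched test/control pair with condition-specific regions
#'
#' Both samples share the specification's spikes and have independent
#' Poisson noise;
#' `dmrSpikes` are additionally enriched only in the test sample, so they
#' are the ground-truth differentially marked regions.
#'
#' @param spec Shared [SimSpec-class].
#' @param dmrSpikes `GRanges` with `fold`, `shape`; must not overlap the
#'   shared spikes.
#' @param seed Optional integer seed.
#' @return `list(test = GRanges, control = GRanges, truth = GRanges)`.
#' @export
simulatePair <- function(spec, dmrSpikes, seed = NULL) {
  if (length(spec@spikes) && length(dmrSpikes) &&
      any(countOverlaps(dmrSpikes, spec@spikes) > 0))
    stop("dmrSpikes must not overlap the shared spikes")
  testSpikes <- sort(c(spec@spikes, dmrSpikes))
  testSpec <- spec
  testSpec@spikes <- testSpikes
  s1 <- if (is.null(seed)) NULL else as.integer(seed)
  s2 <- if (is.null(seed)) NULL else as.integer(seed) + 1L
  list(test = simulateReads(testSpec, seed = s1)$reads,
       control = simulateReads(spec, seed = s2)$reads,
       truth = dmrSpikes)
}

#' Score called peaks against the ground truth
#'
#' Recall = fraction of truth intervals overlapped (>= 1 bp) by at least one
#' call; precision = fraction of calls overlapping at least one truth
#' interval. With zero calls precision is reported as 1 and flagged via
#' `nCalled`.
#'
#' @param called `GRanges` of calls.
#' @param truth `GRanges` of true intervals.
#' @return `list(recall, precision, nCalled)`.
#' @export
scoreAgainstTruth <- function(called, truth) {
  recall <- if (length(truth))
    mean(countOverlaps(truth, called, ignore.strand = TRUE) > 0) else NA_real_
  precision <- if (length(called))
    mean(countOverlaps(called, truth, ignore.strand = TRUE) > 0) else 1
  list(recall = recall, precision = precision, nCalled = length(called))
}
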