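# Peak significance: randomized empirical null (one-sample), exact binomial
# test (two-sample), BH-FDR, and the control-swap DMR merge.

#' Build the randomized empirical null for one-sample significance
#'
#' Draws `P` interval lengths with replacement from the putative-peak length
#' distribution, places each at a uniform position (chromosome chosen
#' proportional to the number of valid starts for that length, interval
#' fully inside the chromosome), and tallies the frequency F(R) of shifted
#' read centers R inside each randomized interval. The null is built from
#' the same sample's raw reads (self-null), so no distributional assumption
#' about the background is made.
#'
#' @param peaks Putative peaks (`GRanges`, >= 1).
#' @param centers [ReadCenters-class] of the same sample.
#' @param P Number of randomized intervals (default 1e6, >= 1e4).
#' @param seed Optional integer seed.
#' @return A [RandomizedNull-class].
#' @export
buildRandomizedNull <- function(peaks, centers, P = 1e6, seed = NULL) {
  if (!length(peaks)) stop("need at least one putative peak")
  P <- as.integer(P)
  if (P < 1e4) stop("P must be at least 10^4")
  sl <- GenomeInfoDb::seqlengths(centers@seqinfo)
  lens <- width(peaks)
  if (max(lens) > max(sl))
    stop("a putative peak is longer than every chromosome")
  withSeed(seed, {
    drawn <- sample(lens, P, replace = TRUE)
    counts <- integer(P)
    for (len in unique(drawn)) {
      i <- which(drawn == len)
      nvalid <- pmax(sl - len + 1L, 0L)
      if (!any(nvalid > 0))
        stop("randomized interval length ", len, " fits no chromosome")
      chr <- sample.int(length(sl), length(i), replace = TRUE, prob = nvalid)
      start0 <- floor(runif(length(i)) * nvalid[chr])  # 0-based
      for (ci in unique(chr)) {
        j <- chr == ci
        p <- centers@positions[[names(sl)[ci]]]
        if (is.null(p) || !length(p)) next
        s0 <- start0[j]
        counts[i[j]] <- findInterval(s0 + len - 0.5, p) -
          findInterval(s0 - 0.5, p)
      }
    }
    freq <- tabulate(counts + 1L, nbins = max(counts) + 1L)
    new("RandomizedNull", freq = as.integer(freq), total = P,
        tailGE = rev(cumsum(rev(as.numeric(freq)))),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

#' One-sample empirical p-value for a peak read count
#'
#' Tail probability of observing at least `r` reads in a length-matched,
#' position-randomized interval: `p = (1 + #\{R >= r\}) / (P + 1)`. The +1
#' pseudocount (the standard permutation-test correction) keeps p strictly
#' positive; it differs from the raw tail sum by at most 1/P. Vectorized and
#' non-increasing in `r`.
#'
#' @param r Integer read count(s), >= 0.
#' @param null A [RandomizedNull-class].
#' @return p-value(s) in (0, 1].
#' @export
oneSamplePValue <- function(r, null) {
  r <- as.integer(r)
  if (any(r < 0)) stop("read counts must be >= 0")
  maxR <- length(null@freq) - 1L
  nGE <- ifelse(r > maxR, 0, null@tailGE[pmin(r, maxR) + 1L])
  (1 + nGE) / (null@total + 1)
}

#' Exact binomial test between test and control read counts
#'
#' Counts are first scaled to reads per million and rounded to integers
#' (`T_norm`, `C_norm`); under the null that a read is equally likely to come
#' from either library, `T_norm` is Binomial(`t` = T_norm + C_norm, 1/2).
#' The default two-sided p-value is the minimum-likelihood sum (all outcomes
#' no more probable than the observed one), which for the symmetric
#' Binomial(t, 1/2) reduces to both tails beyond the observed count and its
#' mirror; `alternative = "greater"` gives the upper-tail probability of at
#' least `T_norm` successes. `normalize = FALSE` instead tests the raw
#' counts against success probability `libT / (libT + libC)` (no rounding;
#' statistically cleaner at low counts).
#'
#' @param testCount,controlCount Non-negative raw read counts (vectors).
#' @param libT,libC Library sizes (> 0).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param normalize Scale both counts to per-million and round (default).
#' @return `data.frame(pValue, testNorm, controlNorm)`.
#' @export
binomialTwoSample <- function(testCount, controlCount, libT, libC,
                              alternative = c("two.sided", "greater"),
                              normalize = TRUE) {
  alternative <- match.arg(alternative)
  if (any(testCount < 0) || any(controlCount < 0))
    stop("read counts must be >= 0")
  stopifnot(libT > 0, libC > 0)
  if (normalize) {
    Tn <- round(testCount * 1e6 / libT)
    Cn <- round(controlCount * 1e6 / libC)
    prob <- 0.5
  } else {
    Tn <- testCount
    Cn <- controlCount
    prob <- libT / (libT + libC)
  }
  t <- Tn + Cn
  if (alternative == "greater") {
    p <- ifelse(t == 0, 1, pbinom(Tn - 1, t, prob, lower.tail = FALSE))
  } else if (normalize) {
    # symmetric case: minimum-likelihood region = both tails at the observed
    # count and its mirror t - Tn
    lo <- pmin(Tn, Cn)
    hi <- pmax(Tn, Cn)
    p <- ifelse(t == 0, 1,
                pbinom(lo, t, 0.5) + pbinom(hi - 1, t, 0.5,
                                            lower.tail = FALSE))
    p <- pmin(p, 1)
  } else {
    p <- vapply(seq_along(t), function(i) {
      if (t[i] == 0) return(1)
      d <- dbinom(0:t[i], t[i], prob)
      sum(d[d <= d[Tn[i] + 1L] * (1 + 1e-7)])
    }, numeric(1))
    p <- pmin(p, 1)
  }
  # extreme imbalances can underflow the double tail sum to exactly 0;
  # clamp so downstream BH/log reporting stays defined
  p <- pmin(pmax(p, 1e-300), 1)
  data.frame(pValue = p, testNorm = Tn, controlNorm = Cn)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment applied genome-wide over all tested peaks.
#'
#' @param p p-values in (0, 1].
#' @return q-values in input order.
#' @export
bhFDR <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Merge forward and swapped differential regions
#'
#' Keeps regions with `qValue < alpha` from the forward (peaks called on the
#' test sample) and reverse (peaks called on the control) passes, unions
#' intervals that overlap by at least 1 bp, and annotates each merged DMR
#' with the contributing direction label(s) and the minimum q-value.
#'
#' @param forward,reverse `GRanges` with mcols `qValue` and `direction`.
#' @param alpha FDR cutoff (default 0.05).
#' @return Non-redundant `GRanges` with mcols `direction` (comma-joined
#'   labels) and `qValue` (minimum over contributors).
#' @export
swapMerge <- function(forward, reverse, alpha = 0.05) {
  keep <- function(x) x[!is.na(mcols(x)$qValue) & mcols(x)$qValue < alpha]
  contrib <- c(keep(forward), keep(reverse))
  if (!length(contrib)) {
    out <- GRanges()
    mcols(out)$direction <- character()
    mcols(out)$qValue <- numeric()
    return(out)
  }
  merged <- reduce(contrib, ignore.strand = TRUE)
  hits <- findOverlaps(merged, contrib, ignore.strand = TRUE)
  dir <- vapply(split(subjectHits(hits), queryHits(hits)), function(i) {
    paste(sort(unique(mcols(contrib)$direction[i])), collapse = ",")
  }, character(1))
  qmin <- vapply(split(subjectHits(hits), queryHits(hits)), function(i) {
    min(mcols(contrib)$qValue[i])
  }, numeric(1))
  mcols(merged)$direction <- unname(dir)
  mcols(merged)$qValue <- unname(qmin)
  merged
}
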