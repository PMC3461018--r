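# Shared fixtures: all synthetic, built in code.

library(GenomicRanges)

smallGenome <- function(len1 = 6e5, len2 = 4e5) {
  GenomeInfoDb::Seqinfo(c("chrA", "chrB"), c(len1, len2))
}

# GRanges of reads from 0-based BED-style coordinates
makeReads <- function(chrom, start0, end0, strand, genome) {
  GRanges(chrom, IRanges(start = start0 + 1L, end = end0),
          strand = strand, seqinfo = genome)
}

# ReadCenters directly from 0-based positions
makeCenters <- function(positions, genome) {
  positions <- lapply(positions, function(p) sort(as.integer(p)))
  all <- stats::setNames(
    vector("list", length(GenomeInfoDb::seqnames(genome))),
    GenomeInfoDb::seqnames(genome))
  for (chr in names(all)) all[[chr]] <- integer(0)
  for (chr in names(positions)) all[[chr]] <- positions[[chr]]
  new("ReadCenters", positions = all, seqinfo = genome,
      librarySize = sum(lengths(all)))
}

# WindowTrack from per-chromosome count vectors (chrom lengths inferred)
makeTrack <- function(counts, windowSize = 200L, librarySize = NULL) {
  genome <- GenomeInfoDb::Seqinfo(names(counts),
                                  lengths(counts) * windowSize)
  if (is.null(librarySize)) librarySize <- round(sum(unlist(counts)))
  new("WindowTrack", counts = lapply(counts, as.numeric),
      windowSize = as.integer(windowSize),
      librarySize = as.integer(librarySize), normalized = FALSE,
      seqinfo = genome)
}

writeTempBed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

# Small punctate simulation shared by pipeline tests (fast settings)
quickPunctateSim <- function(seed = 3L, nSpikes = 6L, fold = 20) {
  genome <- GenomeInfoDb::Seqinfo(c("chrA", "chrB"), c(15e5, 1e6))
  spikes <- tileSpikes(genome, nSpikes, c(1000, 1000), fold = fold,
                       seed = seed)
  sim <- simulateReads(simSpec(genome, backgroundRate = 0.5,
                               spikes = spikes), seed = seed + 50L)
  list(genome = genome, spikes = spikes, reads = sim$reads)
}
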