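#' Read a chromosome-sizes table
#'
#' Parses a two-column (name, length in bp) whitespace-delimited table into a
#' [GenomeInfoDb::Seqinfo] genome definition.
#'
#' @param path Path to the chrom.sizes file.
#' @return A [GenomeInfoDb::Seqinfo].
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome names")
  if (any(tab$length <= 0)) stop("chromosome lengths must be positive")
  Seqinfo(seqnames = as.character(tab$chrom), seqlengths = tab$length)
}

#' Read aligned reads from a 6-column BED file
#'
#' Parses whitespace-delimited BED (chrom, start, end, name, score, strand;
#' columns 4-5 are ignored) into a stranded [GenomicRanges::GRanges]. Reads
#' on chromosomes absent from `genome` are skipped with a warning. Malformed
#' lines (non-integer coordinates, start >= end, strand other than `+`/`-`)
#' abort with the offending line number. Gzip-compressed files are read
#' transparently.
#'
#' @param path Path to the BED file (optionally gzipped).
#' @param genome A [GenomeInfoDb::Seqinfo] genome definition.
#' @param verbose Emit a message about skipped reads.
#' @return A `GRanges` of reads, in file order (1-based coordinates).
#' @export
readBed <- function(path, genome, verbose = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GRanges(seqinfo = genome)
    return(gr)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop(sprintf("line %d: expected 6 BED columns, found %d",
                 lineno[which(nf < 6L)[1L]], min(nf)))
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  str <- vapply(fields, `[[`, "", 6L)
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("line %d: non-integer coordinates", lineno[bad[1L]]))
  bad <- which(start0 >= end0 | start0 < 0L)
  if (length(bad))
    stop(sprintf("line %d: requires 0 <= start < end", lineno[bad[1L]]))
  bad <- which(!str %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("line %d: strand must be '+' or '-'", lineno[bad[1L]]))
  known <- chrom %in% GenomeInfoDb::seqnames(genome)
  if (!all(known)) {
    vmsg(verbose, "skipping %d read(s) on chromosomes absent from genome",
         sum(!known))
  }
  GRanges(chrom[known],
          IRanges(start = start0[known] + 1L, end = end0[known]),
          strand = str[known], seqinfo = genome)
}

#' Remove duplicate reads
#'
#' Keeps at most one read per (chrom, start, end, strand) tuple — the most
#' conservative PCR-duplicate definition for single-end reads — retaining
#' the first occurrence.
#'
#' @param reads A `GRanges` of reads.
#' @param verbose Log the retention count.
#' @return The deduplicated `GRanges`, in input order.
#' @export
deduplicateReads <- function(reads, verbose = TRUE) {
  if (!length(reads)) return(reads)
  key <- paste(as.character(seqnames(reads)), start(reads), end(reads),
               as.character(strand(reads)), sep = "\r")
  keep <- !duplicated(key)
  vmsg(verbose, "retained %d of %d reads after deduplication",
       sum(keep), length(reads))
  reads[keep]
}

#' Shift reads to fragment centers
#'
#' Each read is replaced by a single point: the position `shift` bp downstream
#' of its 5' end, representing the center of the sequenced DNA fragment
#' (default 95 bp, half of a ~190 bp mononucleosomal fragment). Positions are
#' clamped to the chromosome, so no read is lost.
#'
#' @param reads A stranded `GRanges` of reads.
#' @param shift Non-negative shift in bp from the 5' end.
#' @param genome A [GenomeInfoDb::Seqinfo]; defaults to `seqinfo(reads)`.
#' @return A [ReadCenters-class] with per-chromosome sorted 0-based positions.
#' @export
shiftReads <- function(reads, shift = 95L, genome = seqinfo(reads)) {
  stopifnot(shift >= 0)
  shift <- as.integer(shift)
  sl <- GenomeInfoDb::seqlengths(genome)
  if (any(is.na(sl))) stop("genome must have defined chromosome lengths")
  chrom <- as.character(seqnames(reads))
  plus <- as.character(strand(reads)) == "+"
  pos0 <- ifelse(plus, (start(reads) - 1L) + shift, (end(reads) - 1L) - shift)
  pos0 <- pmax(0L, pmin(as.integer(pos0), sl[chrom] - 1L))
  positions <- lapply(stats::setNames(nm = names(sl)), function(chr) {
    sort(as.integer(pos0[chrom == chr]))
  })
  new("ReadCenters", positions = positions, seqinfo = genome,
      librarySize = length(reads))
}

#' Bin read centers into fixed windows
#'
#' Counts shifted fragment centers in non-overlapping windows of
#' `windowSize` bp (window i covers 0-based bp `[i*w, (i+1)*w)`; the last
#' window may be short).
#'
#' @param centers A [ReadCenters-class].
#' @param windowSize Window width in bp (default 200).
#' @return A raw-count [WindowTrack-class].
#' @export
binCounts <- function(centers, windowSize = 200L) {
  stopifnot(windowSize > 0)
  windowSize <- as.integer(windowSize)
  sl <- GenomeInfoDb::seqlengths(centers@seqinfo)
  counts <- lapply(stats::setNames(nm = names(sl)), function(chr) {
    nw <- as.integer(ceiling(sl[[chr]] / windowSize))
    p <- centers@positions[[chr]]
    if (is.null(p) || !length(p)) return(numeric(nw))
    as.numeric(tabulate(p %/% windowSize + 1L, nbins = nw))
  })
  new("WindowTrack", counts = counts, windowSize = windowSize,
      librarySize = centers@librarySize, normalized = FALSE,
      seqinfo = centers@seqinfo)
}

#' Scale a window track to reads per million
#'
#' Multiplies every window count by `1e6 / librarySize`. Used for reporting
#' and cross-sample comparison; peak calling itself runs on raw counts (the
#' Monte Carlo thresholds are learned from the same track, so calling is
#' invariant to this global rescaling).
#'
#' @param track A raw [WindowTrack-class].
#' @return The per-million-normalized track.
#' @export
normalizePerMillion <- function(track) {
  if (track@normalized) stop("track is already normalized")
  if (track@librarySize <= 0L) stop("librarySize must be positive")
  f <- 1e6 / track@librarySize
  track@counts <- lapply(track@counts, function(v) v * f)
  track@normalized <- TRUE
  track
}

#' Write / read a window track as bedGraph
#'
#' `writeBedGraph()` writes the track run-length collapsed (zero runs
#' included) as 4-column bedGraph; `readBedGraph()` reconstructs the window
#' vectors given the same genome and window size, so a written track
#' round-trips exactly.
#'
#' @param track A [WindowTrack-class].
#' @param path Output/input path.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param windowSize Window width the file was written with.
#' @param librarySize,normalized Track metadata to restore.
#' @return `readBedGraph()` returns a [WindowTrack-class].
#' @export
writeBedGraph <- function(track, path) {
  sl <- GenomeInfoDb::seqlengths(track@seqinfo)
  rows <- lapply(names(track@counts), function(chr) {
    v <- track@counts[[chr]]
    r <- rle(v)
    endw <- cumsum(r$lengths)
    startw <- endw - r$lengths
    data.frame(chrom = chr, start = startw * track@windowSize,
               end = pmin(endw * track@windowSize, sl[[chr]]),
               value = r$values)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeBedGraph
#' @export
readBedGraph <- function(path, genome, windowSize = 200L,
                         librarySize = 0L, normalized = FALSE) {
  windowSize <- as.integer(windowSize)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "value"))
  sl <- GenomeInfoDb::seqlengths(genome)
  counts <- lapply(stats::setNames(nm = names(sl)), function(chr) {
    nw <- as.integer(ceiling(sl[[chr]] / windowSize))
    v <- numeric(nw)
    sub <- tab[tab$chrom == chr, , drop = FALSE]
    if (nrow(sub)) {
      w1 <- sub$start %/% windowSize + 1L
      w2 <- pmin(as.integer(ceiling(sub$end / windowSize)), nw)
      for (i in seq_len(nrow(sub))) v[w1[i]:w2[i]] <- sub$value[i]
    }
    v
  })
  new("WindowTrack", counts = counts, windowSize = windowSize,
      librarySize = as.integer(librarySize), normalized = normalized,
      seqinfo = genome)
}

#' Write scored peaks as BED6+
#'
#' Columns: chrom, start (0-based), end, name, score (`-log10(q)`, capped at
#' 1000), strand (`.`), then readCount, pValue, qValue, maxPower, and — for
#' two-sample results — testNorm, controlNorm, fold and direction.
#'
#' @param peaks A `GRanges` of scored peaks.
#' @param path Output path.
#' @export
writePeaks <- function(peaks, path) {
  if (!length(peaks)) {
    file.create(path)
    return(invisible(path))
  }
  q <- mcols(peaks)$qValue
  score <- round(pmin(-log10(pmax(q, 1e-300)), 1000), 3)
  tab <- data.frame(chrom = as.character(seqnames(peaks)),
                    start = start(peaks) - 1L, end = end(peaks),
                    name = sprintf("peak_%d", seq_along(peaks)),
                    score = score, strand = ".",
                    readCount = mcols(peaks)$readCount,
                    pValue = signif(mcols(peaks)$pValue, 6),
                    qValue = signif(q, 6),
                    maxPower = signif(mcols(peaks)$maxPower, 6))
  for (col in c("testNorm", "controlNorm", "fold", "direction")) {
    if (!is.null(mcols(peaks)[[col]])) tab[[col]] <- mcols(peaks)[[col]]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write simulated reads as 6-column BED
#'
#' @param reads A stranded `GRanges`.
#' @param path Output path.
#' @export
writeReadsBed <- function(reads, path) {
  tab <- data.frame(chrom = as.character(seqnames(reads)),
                    start = start(reads) - 1L, end = end(reads),
                    name = sprintf("r%d", seq_along(reads)), score = 0L,
                    strand = as.character(strand(reads)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
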