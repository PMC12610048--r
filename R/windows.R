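#' Tile contigs into fixed-size sliding windows
#'
#' Windows start at the first base of each contig and advance by `step`;
#' the final window on a contig is truncated at the contig end if its start
#' is still in range. The defaults reproduce the published screen settings
#' (window 500 bp, step 1000 bp); note that with `step > window` the tiling
#' leaves uncovered gaps, which triggers a warning.
#'
#' @param contig_lengths named vector of contig lengths in bp.
#' @param window window size in bp.
#' @param step distance between successive window starts in bp.
#' @return a sorted `GRanges` of windows (1-based inclusive, with
#'   `seqlengths` set).
#' @examples
#' make_windows(c(chr1 = 3000), window = 500, step = 500)
#' @export
make_windows <- function(contig_lengths, window = 500L, step = 1000L) {
  if (window <= 0 || step <= 0) stop_("window and step must be positive")
  if (is.null(names(contig_lengths))) stop_("contig_lengths must be named")
  if (step > window)
    warning(sprintf(
      "step (%d) exceeds window (%d): the tiling leaves %d-bp gaps between windows",
      as.integer(step), as.integer(window), as.integer(step - window)),
      call. = FALSE)
  pieces <- lapply(names(contig_lengths), function(ctg) {
    len <- as.integer(contig_lengths[[ctg]])
    starts <- seq.int(1L, len, by = as.integer(step))
    GenomicRanges::GRanges(ctg, IRanges::IRanges(
      start = starts, end = pmin(starts + as.integer(window) - 1L, len)))
  })
  gr <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlevels(gr) <- names(contig_lengths)
  GenomeInfoDb::seqlengths(gr) <- as.integer(contig_lengths)
  gr
}

#' Read-counting filters
#'
#' Which records are eligible for window counting, and how a read is
#' assigned to windows. The defaults drop unmapped, secondary,
#' supplementary and duplicate records and apply no mapping-quality cut,
#' mirroring an analysis in which duplicates were removed upstream and no
#' MAPQ threshold was stated.
#'
#' @param min_mapq minimum mapping quality (records below are ignored).
#' @param exclude subset of `c("unmapped", "secondary", "supplementary",
#'   "duplicate")`: records with any of these SAM flags set are ignored.
#' @param assignment_mode `"start"` assigns a read to every window
#'   containing its leftmost aligned position (each read counted exactly
#'   once in a non-overlapping tiling); `"overlap"` assigns it to every
#'   window its aligned span overlaps.
#' @return an object of class `count_filters`.
#' @export
count_filters <- function(min_mapq = 0L,
                          exclude = c("unmapped", "secondary",
                                      "supplementary", "duplicate"),
                          assignment_mode = c("start", "overlap")) {
  if (min_mapq < 0) stop_("min_mapq must be >= 0")
  exclude <- if (length(exclude))
    match.arg(exclude, c("unmapped", "secondary", "supplementary",
                         "duplicate"), several.ok = TRUE)
  else character()
  structure(list(min_mapq = as.integer(min_mapq), exclude = exclude,
                 assignment_mode = match.arg(assignment_mode)),
            class = "count_filters")
}

FLAG_BITS <- c(unmapped = 0x4L, secondary = 0x100L, duplicate = 0x400L,
               supplementary = 0x800L)

filter_records <- function(aln, filters) {
  keep <- aln$mapq >= filters$min_mapq
  for (f in filters$exclude)
    keep <- keep & bitwAnd(aln$flag, FLAG_BITS[[f]]) == 0L
  aln[keep, , drop = FALSE]
}

check_sorted <- function(aln, contigs) {
  if (nrow(aln) == 0L) return(invisible(TRUE))
  unknown <- !(aln$rname %in% contigs)
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop_("record '%s' maps to unknown contig '%s'", aln$qname[i], aln$rname[i])
  }
  key <- match(aln$rname, contigs)
  # first record whose (contig, pos) key falls below its predecessor's
  bad <- which(diff(key) < 0L | (diff(key) == 0L & diff(aln$pos) < 0L)) + 1L
  if (length(bad)) {
    i <- bad[1]
    stop_("alignments are not coordinate-sorted: record '%s' (%s:%d) is out of order",
          aln$qname[i], aln$rname[i], aln$pos[i])
  }
  invisible(TRUE)
}

#' Count filtered reads per window
#'
#' Assigns each eligible record to windows according to the filters'
#' `assignment_mode` and returns the windows with a `count` metadata
#' column, in window order. Input must be coordinate-sorted (contigs
#' grouped, positions non-decreasing).
#'
#' @param aln alignment data.frame ([simulate_pool()] / [read_alignments()]).
#' @param windows `GRanges` from [make_windows()].
#' @param filters a [count_filters()].
#' @return `windows` with an integer metadata column `count` and an
#'   attribute `n_filtered_reads` (records passing the filters).
#' @export
count_reads <- function(aln, windows, filters = count_filters()) {
  contigs <- GenomeInfoDb::seqlevels(windows)
  check_sorted(aln, contigs)
  kept <- filter_records(aln, filters)
  if (nrow(kept)) {
    reads <- GenomicRanges::GRanges(
      kept$rname,
      if (filters$assignment_mode == "start")
        IRanges::IRanges(start = kept$pos, width = 1L)
      else
        IRanges::IRanges(start = kept$pos, width = kept$qwidth),
      seqinfo = GenomeInfoDb::seqinfo(windows))
    n <- GenomicRanges::countOverlaps(windows, reads)
  } else {
    n <- integer(length(windows))
  }
  out <- windows
  S4Vectors::mcols(out)$count <- n
  S4Vectors::metadata(out)$n_filtered_reads <- nrow(kept)
  out
}

#' Write per-window counts as TSV
#'
#' Columns `contig`, `start`, `end`, `count`; intervals are written
#' 0-based half-open (BED-style), matching the package's interval outputs.
#'
#' @param counts `GRanges` with a `count` column from [count_reads()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_counts_tsv <- function(counts, file) {
  df <- data.frame(contig = as.character(GenomeInfoDb::seqnames(counts)),
                   start = GenomicRanges::start(counts) - 1L,
                   end = GenomicRanges::end(counts),
                   count = S4Vectors::mcols(counts)$count)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
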