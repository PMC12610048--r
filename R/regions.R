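#' Merge retained windows into candidate male-specific regions
#'
#' Retained windows whose separation is at most `merge_gap` bp (overlapping
#' or bookended when `merge_gap = 0`) are unioned into one region, and
#' per-region aggregates are computed from the contributing windows.
#'
#' @param retained retained `GRanges` from [select_windows()] (any order;
#'   sorted internally).
#' @param merge_gap maximum gap in bp across which windows are still merged.
#' @return a sorted, disjoint `GRanges` of regions with metadata columns
#'   `n_windows`, `min_CQ` and `sum_Hm`.
#' @export
merge_windows <- function(retained, merge_gap = 0L) {
  retained <- GenomicRanges::sort(retained)
  regions <- GenomicRanges::reduce(GenomicRanges::granges(retained),
                                   min.gapwidth = as.integer(merge_gap) + 1L)
  hits <- GenomicRanges::findOverlaps(retained, regions)
  j <- S4Vectors::subjectHits(hits)
  m <- S4Vectors::mcols(retained)
  has_stats <- all(c("CQ", "Hm") %in% colnames(m))
  S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
    n_windows = as.integer(tabulate(j, nbins = length(regions))),
    min_CQ = if (has_stats && length(j))
      as.numeric(tapply(m$CQ[S4Vectors::queryHits(hits)], factor(j, levels = seq_along(regions)), min))
      else rep(NA_real_, length(regions)),
    sum_Hm = if (has_stats && length(j))
      as.integer(tapply(m$Hm[S4Vectors::queryHits(hits)], factor(j, levels = seq_along(regions)), sum))
      else rep(NA_integer_, length(regions)))
  regions
}

#' Interval length under an explicit coordinate convention
#'
#' Published interval sizes mix two conventions: half-open spans
#' (`end - start`) and 1-based inclusive sizes (`end - start + 1`). Both
#' are provided so printed coordinates can be reproduced either way.
#'
#' @param start,end numeric vectors of interval bounds in the stated
#'   convention (`start <= end`).
#' @param convention `"half_open"` or `"inclusive"`.
#' @return integer vector of lengths in bp.
#' @examples
#' region_length(2906224, 2907256, "half_open")   # 1032
#' region_length(33626816, 33627324, "inclusive") # 509
#' @export
region_length <- function(start, end, convention = c("half_open", "inclusive")) {
  convention <- match.arg(convention)
  len <- if (convention == "half_open") end - start else end - start + 1
  if (any(len < 0)) stop_("negative interval length (start > end)")
  as.integer(len)
}

#' Extract region sequence with flanks for primer design
#'
#' Returns each region's sequence extended by `flank` bp on each side,
#' clamped at the contig boundaries. Record names encode the contig and
#' the 1-based inclusive coordinates of the extended interval, e.g.
#' `"chr8:33625816-33628324"`.
#'
#' @param regions `GRanges` of regions (e.g. from [merge_windows()]).
#' @param reference the reference as a `DNAStringSet` or a FASTA path.
#' @param flank bp of flanking sequence on each side (default 1 kb, the
#'   span used for published primer design).
#' @return a `DNAStringSet`, one record per region.
#' @export
extract_flanks <- function(regions, reference, flank = 1000L) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  ctg <- as.character(GenomeInfoDb::seqnames(regions))
  unknown <- !(ctg %in% names(reference))
  if (any(unknown)) stop_("unknown contig '%s'", ctg[which(unknown)[1]])
  len <- Biostrings::width(reference)[match(ctg, names(reference))]
  from <- pmax(1L, GenomicRanges::start(regions) - as.integer(flank))
  to <- pmin(len, GenomicRanges::end(regions) + as.integer(flank))
  out <- Biostrings::DNAStringSet(vapply(seq_along(regions), function(i) {
    as.character(Biostrings::subseq(reference[[ctg[i]]], from[i], to[i]))
  }, ""))
  names(out) <- sprintf("%s:%d-%d", ctg, from, to)
  out
}

#' Write regions as BED and as a 1-based report with aggregates
#'
#' `write_regions_bed()` writes standard 0-based half-open BED;
#' `write_regions_tsv()` writes a human-readable table in 1-based
#' inclusive coordinates with the per-region aggregates and both length
#' conventions.
#'
#' @param regions `GRanges` from [merge_windows()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(regions, file) {
  gr <- GenomicRanges::granges(regions)
  names(gr) <- sprintf("region_%d", seq_along(gr))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname write_regions_bed
#' @export
write_regions_tsv <- function(regions, file) {
  m <- S4Vectors::mcols(regions)
  df <- data.frame(
    contig = as.character(GenomeInfoDb::seqnames(regions)),
    start_1based = GenomicRanges::start(regions),
    end_1based = GenomicRanges::end(regions),
    length_bp = GenomicRanges::width(regions),
    n_windows = m$n_windows, min_CQ = m$min_CQ, sum_Hm = m$sum_Hm)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
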