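#' Write alignment records as a coordinate-sorted SAM file
#'
#' Emits a minimal valid SAM 1.6 file (header `@HD`/`@SQ` plus 11-column
#' records, quality string `*`). No installed R package writes SAM records
#' from scratch, so the text is produced directly; the files round-trip
#' through `samtools`/`Rsamtools`.
#'
#' @param aln alignment data.frame as returned by [simulate_pool()].
#' @param file output path (`.sam`).
#' @param contig_lengths named vector of contig lengths; defaults to the
#'   `contig_lengths` attribute of `aln`.
#' @return the path, invisibly.
#' @export
write_sam <- function(aln, file, contig_lengths = attr(aln, "contig_lengths")) {
  if (is.null(contig_lengths)) stop_("contig_lengths is required")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      as.integer(contig_lengths)))
  body <- if (nrow(aln)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
            aln$seq)
  } else character()
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read aligned records from SAM or BAM into the package's record table
#'
#' SAM input is converted with [Rsamtools::asBam()] and then scanned; BAM
#' is scanned directly. Records keep their file order, which for the
#' coordinate-sorted inputs this pipeline expects is coordinate order.
#'
#' @param file path to a `.sam` or `.bam` file.
#' @return alignment data.frame with columns `qname`, `flag`, `rname`,
#'   `pos`, `mapq`, `cigar`, `qwidth`, `seq` and attribute
#'   `contig_lengths`.
#' @export
read_alignments <- function(file) {
  bam <- if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    Rsamtools::asBam(file, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else file
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "qwidth", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  aln <- data.frame(qname = x$qname, flag = x$flag,
                    rname = as.character(x$rname), pos = x$pos,
                    mapq = x$mapq, cigar = x$cigar, qwidth = x$qwidth,
                    seq = as.character(x$seq), stringsAsFactors = FALSE)
  attr(aln, "contig_lengths") <- hdr
  aln
}
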