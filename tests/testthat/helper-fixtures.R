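# shared builders and independent oracles

# alignment record table with sensible defaults; pos is 1-based leftmost
aln_df <- function(pos, rname = "chr1", flag = 0L, mapq = 60L, qwidth = 100L,
                   contig_lengths = c(chr1 = 10000L)) {
  n <- length(pos)
  qw <- rep_len(as.integer(qwidth), n)
  df <- data.frame(
    qname = sprintf("r%03d", seq_len(n)),
    flag = rep_len(as.integer(flag), n),
    rname = rep_len(rname, n),
    pos = as.integer(pos),
    mapq = rep_len(as.integer(mapq), n),
    cigar = if (n) paste0(qw, "M") else character(),
    qwidth = qw,
    seq = if (n) strrep("A", qw) else character(),
    stringsAsFactors = FALSE)
  attr(df, "contig_lengths") <- contig_lengths
  df
}

# brute-force read x window double loop, written independently of count_reads
brute_count <- function(aln, windows, min_mapq = 0L, exclude = character(),
                        mode = "start") {
  bits <- c(unmapped = 4L, secondary = 256L, duplicate = 1024L,
            supplementary = 2048L)
  ws <- GenomicRanges::start(windows)
  we <- GenomicRanges::end(windows)
  wc <- as.character(GenomeInfoDb::seqnames(windows))
  out <- integer(length(windows))
  for (i in seq_len(nrow(aln))) {
    if (aln$mapq[i] < min_mapq) next
    drop <- FALSE
    for (f in exclude)
      if (bitwAnd(aln$flag[i], bits[[f]]) != 0L) drop <- TRUE
    if (drop) next
    rs <- aln$pos[i]
    re <- aln$pos[i] + aln$qwidth[i] - 1L
    for (w in seq_along(windows)) {
      if (wc[w] != aln$rname[i]) next
      hit <- if (mode == "start") rs >= ws[w] && rs <= we[w]
             else rs <= we[w] && re >= ws[w]
      if (hit) out[w] <- out[w] + 1L
    }
  }
  out
}

# count-bearing GRanges from raw integers, for compute_cq inputs
counts_gr <- function(counts, width = 500L, step = width,
                      contig = "chr1") {
  n <- length(counts)
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(
    start = 1L + (seq_len(n) - 1L) * step, width = width))
  S4Vectors::mcols(gr)$count <- as.integer(counts)
  S4Vectors::metadata(gr)$n_filtered_reads <- sum(counts)
  gr
}

# the standard synthetic study genome: one 500-kb contig with one 3-kb
# Y-specific insertion in the middle
study_spec <- function(seed = 7L, with_insertion = TRUE) {
  sex_genome_spec(
    c(chr1 = 500000),
    insertions = if (with_insertion)
      data.frame(contig = "chr1", start = 250001L, length = 3000L),
    base_seed = seed)
}

study_params <- function(seed = 7L) {
  list(male = read_sim_params(depth = 20, seed = seed * 10L),
       female = read_sim_params(depth = 26, seed = seed * 10L + 1L))
}
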