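#' Specification of a synthetic XY genome
#'
#' Describes a male-derived reference genome carrying Y-specific insertions.
#' The reference is Y-inclusive: insertion intervals are *present* in the
#' reference sequence, and the X haplotype is defined as the reference with
#' those intervals excised. Under this construction female (XX) pools can
#' never produce reads from inside an insertion, which is exactly the
#' coverage-dropout signal the chromosome-quotient screen detects.
#'
#' @param contigs named numeric vector of contig lengths in bp, or a
#'   data.frame with columns `name` and `length`.
#' @param insertions `NULL`, or a data.frame with columns `contig`,
#'   `start` (1-based first reference base of the insertion) and `length`
#'   (bp). Intervals must be non-overlapping and strictly inside their
#'   contig (they may not touch either contig end, so every insertion has
#'   flanking sequence on both sides).
#' @param base_seed integer seed used to generate the reference sequence.
#' @param gc_fraction GC content of the generated sequence, in \[0, 1\].
#' @param sequences optional named character vector of explicit contig
#'   sequences; when given, contig lengths are taken from it and no random
#'   sequence is generated. Used to plant engineered loci (e.g. a marker
#'   fixture) into an otherwise synthetic genome.
#' @return an object of class `sex_genome_spec`.
#' @export
sex_genome_spec <- function(contigs, insertions = NULL, base_seed = 1L,
                            gc_fraction = 0.4, sequences = NULL) {
  if (is.data.frame(contigs)) {
    contigs <- setNames(as.numeric(contigs$length), as.character(contigs$name))
  }
  if (!is.null(sequences)) {
    contigs <- setNames(nchar(sequences), names(sequences))
  }
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == ""))
    stop_("contigs must be named")
  if (any(contigs <= 0)) stop_("contig lengths must be positive")
  if (is.null(insertions)) {
    insertions <- data.frame(contig = character(), start = integer(),
                             length = integer())
  }
  insertions <- data.frame(contig = as.character(insertions$contig),
                           start = as.integer(insertions$start),
                           length = as.integer(insertions$length))
  validate_insertions(insertions, contigs)
  structure(list(contigs = contigs, insertions = insertions,
                 base_seed = as.integer(base_seed),
                 gc_fraction = gc_fraction, sequences = sequences),
            class = "sex_genome_spec")
}

validate_insertions <- function(ins, contigs) {
  if (nrow(ins) == 0L) return(invisible(TRUE))
  if (any(ins$length <= 0L)) stop_("insertion lengths must be positive")
  bad <- !(ins$contig %in% names(contigs))
  if (any(bad)) stop_("insertion on unknown contig '%s'", ins$contig[which(bad)[1]])
  end <- ins$start + ins$length - 1L
  # strictly inside: flanking sequence must exist on both sides
  oob <- ins$start <= 1L | end >= contigs[ins$contig]
  if (any(oob)) {
    i <- which(oob)[1]
    stop_("insertion %s:%d-%d is not strictly inside its contig",
          ins$contig[i], ins$start[i], end[i])
  }
  for (ctg in unique(ins$contig)) {
    sub <- ins[ins$contig == ctg, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    e <- sub$start + sub$length - 1L
    if (nrow(sub) > 1L && any(sub$start[-1L] <= e[-nrow(sub)])) {
      i <- which(sub$start[-1L] <= e[-nrow(sub)])[1] + 1L
      stop_("overlapping insertions on %s near position %d", ctg, sub$start[i])
    }
  }
  invisible(TRUE)
}

#' Build a synthetic XY genome from a specification
#'
#' Generates (or adopts) the Y-inclusive reference sequence, records the
#' planted insertion intervals as ground-truth male-specific regions, and
#' derives the X haplotype by excising those intervals, together with an
#' exact coordinate liftover between X-haplotype and reference positions.
#'
#' Deterministic for a fixed `base_seed`.
#'
#' @param spec a [sex_genome_spec()].
#' @return a `sex_genome` list with elements `reference`
#'   (`DNAStringSet`), `x_seq` (`DNAStringSet`, the X haplotype),
#'   `truth_regions` (`GRanges` of insertions in reference coordinates,
#'   identical to `x_edits`), `x_edits`, `x_lengths` (named vector) and
#'   `spec`.
#' @examples
#' spec <- sex_genome_spec(c(chr1 = 10000), data.frame(
#'   contig = "chr1", start = 5001, length = 305), base_seed = 42)
#' g <- build_genome(spec)
#' sum(Biostrings::width(g$x_seq))  # 9695
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "sex_genome_spec"))
  if (!is.null(spec$sequences)) {
    ref_chr <- spec$sequences
  } else {
    ref_chr <- with_seed(spec$base_seed, {
      vapply(spec$contigs, function(n) random_dna(n, spec$gc_fraction), "")
    })
  }
  reference <- Biostrings::DNAStringSet(ref_chr)
  names(reference) <- names(spec$contigs)

  ins <- spec$insertions
  truth <- GenomicRanges::GRanges(
    seqnames = ins$contig,
    ranges = IRanges::IRanges(start = ins$start, width = ins$length),
    seqlengths = round(spec$contigs))
  truth <- GenomicRanges::sort(truth)

  x_seq <- reference
  for (ctg in names(reference)) {
    ed <- truth[GenomeInfoDb::seqnames(truth) == ctg]
    if (length(ed) == 0L) next
    keep <- IRanges::gaps(IRanges::ranges(ed),
                          start = 1L, end = spec$contigs[[ctg]])
    x_seq[[ctg]] <- unlist(Biostrings::extractAt(reference[[ctg]], keep))
  }

  structure(list(reference = reference, x_seq = x_seq,
                 truth_regions = truth, x_edits = truth,
                 x_lengths = setNames(Biostrings::width(x_seq), names(x_seq)),
                 spec = spec),
            class = "sex_genome")
}

edits_for <- function(genome, contig) {
  ed <- genome$x_edits[GenomeInfoDb::seqnames(genome$x_edits) == contig]
  data.frame(start = GenomicRanges::start(ed), end = GenomicRanges::end(ed),
             width = GenomicRanges::width(ed))
}

#' Lift positions between reference and X-haplotype coordinates
#'
#' Both maps are 1-based and exact; the map is a bijection on all positions
#' outside the edited (insertion) intervals. Reference positions inside an
#' insertion have no X image and lift to `NA`.
#'
#' @param genome a `sex_genome` from [build_genome()].
#' @param contig contig name.
#' @param pos integer vector of positions (1-based).
#' @return integer vector of lifted positions.
#' @export
lift_ref_to_x <- function(genome, contig, pos) {
  ed <- edits_for(genome, contig)
  pos <- as.integer(pos)
  out <- rep(NA_integer_, length(pos))
  inside <- rep(FALSE, length(pos))
  removed_before <- integer(length(pos))
  if (nrow(ed)) {
    for (i in seq_len(nrow(ed))) {
      inside <- inside | (pos >= ed$start[i] & pos <= ed$end[i])
      removed_before <- removed_before + ifelse(pos > ed$end[i], ed$width[i], 0L)
    }
  }
  ok <- !inside & pos >= 1L & pos <= genome$spec$contigs[[contig]]
  out[ok] <- pos[ok] - removed_before[ok]
  out
}

#' @rdname lift_ref_to_x
#' @export
lift_x_to_ref <- function(genome, contig, pos) {
  ed <- edits_for(genome, contig)
  pos <- as.integer(pos)
  added <- integer(length(pos))
  if (nrow(ed)) {
    cum <- c(0L, cumsum(ed$width))[seq_len(nrow(ed))]
    x_junction <- ed$start - 1L - cum  # last X base before each insertion
    for (i in seq_len(nrow(ed)))
      added <- added + ifelse(pos > x_junction[i], ed$width[i], 0L)
  }
  out <- pos + added
  out[pos < 1L | pos > genome$x_lengths[[contig]]] <- NA_integer_
  out
}

#' Read-simulation parameters for one sequencing pool
#'
#' @param depth mean fold-coverage of the pool over its haplotypes.
#' @param read_length read length in bp (single-end, fixed length).
#' @param error_rate substitution error probability per base, in \[0, 1).
#' @param seed mandatory integer seed; every pool draws its own stream.
#' @return an object of class `read_sim_params`.
#' @export
read_sim_params <- function(depth, read_length = 150L, error_rate = 0.001,
                            seed) {
  if (missing(seed)) stop_("an explicit integer seed is required")
  stopifnot(depth >= 0, read_length > 0, error_rate >= 0, error_rate < 1)
  structure(list(depth = depth, read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate an aligned, coordinate-sorted sex-pool read set
#'
#' Emulates pooled resequencing of one sex followed by alignment to the
#' Y-inclusive reference. Females draw reads from two X haplotypes; males
#' from one X haplotype and one Y-inclusive (reference) haplotype, each
#' haplotype contributing half the pool depth. Every read is emitted as an
#' ungapped aligned record in reference coordinates. X-derived reads that
#' would span an excision junction (and so could not align ungapped) are
#' dropped, producing a small documented coverage dip at junctions.
#' Substitution errors are applied at `error_rate`; reads are all plus
#' strand with a full-length match CIGAR.
#'
#' @param genome a `sex_genome` from [build_genome()].
#' @param sex `"male"` or `"female"`.
#' @param params a [read_sim_params()].
#' @return a coordinate-sorted data.frame of alignment records with columns
#'   `qname`, `flag`, `rname`, `pos` (1-based leftmost), `mapq`, `cigar`,
#'   `qwidth`, `seq`, carrying the contig lengths as attribute
#'   `contig_lengths`.
#' @export
simulate_pool <- function(genome, sex = c("male", "female"), params) {
  sex <- match.arg(sex)
  stopifnot(inherits(genome, "sex_genome"), inherits(params, "read_sim_params"))
  rl <- params$read_length
  half <- params$depth / 2
  # haplotype templates: "x" samples X coordinates then lifts; "ref" samples
  # reference coordinates directly
  haps <- if (sex == "female") c("x", "x") else c("x", "ref")

  recs <- with_seed(params$seed, {
    out <- list()
    for (ctg in names(genome$reference)) {
      ref_len <- genome$spec$contigs[[ctg]]
      x_len <- genome$x_lengths[[ctg]]
      for (h in haps) {
        hap_len <- if (h == "x") x_len else ref_len
        if (hap_len < rl || half == 0) next
        n <- rpois(1L, half * hap_len / rl)
        if (n == 0L) next
        start <- sample.int(hap_len - rl + 1L, n, replace = TRUE)
        if (h == "x") {
          # drop reads spanning an excision junction: a junction lies after
          # X position j; the read covers X positions [start, start+rl-1]
          ed <- edits_for(genome, ctg)
          if (nrow(ed)) {
            cum <- c(0L, cumsum(ed$width))[seq_len(nrow(ed))]
            xj <- ed$start - 1L - cum
            spans <- rep(FALSE, n)
            for (j in xj) spans <- spans | (start <= j & start + rl - 1L > j)
            start <- start[!spans]
          }
          pos <- lift_x_to_ref(genome, ctg, start)
        } else {
          pos <- start
        }
        if (length(pos))
          out[[length(out) + 1L]] <- data.frame(rname = ctg, pos = pos)
      }
    }
    if (length(out) == 0L) {
      data.frame(rname = character(), pos = integer(), seq = character())
    } else {
      df <- do.call(rbind, out)
      df <- df[order(match(df$rname, names(genome$reference)), df$pos), ,
               drop = FALSE]
      seqs <- character(nrow(df))
      for (ctg in unique(df$rname)) {
        i <- which(df$rname == ctg)
        seqs[i] <- as.character(Biostrings::extractAt(
          genome$reference[[ctg]],
          IRanges::IRanges(start = df$pos[i], width = rl)))
      }
      df$seq <- apply_substitutions(seqs, params$error_rate)
      df
    }
  })

  n <- nrow(recs)
  aln <- data.frame(
    qname = if (n) sprintf("%s_%s_%07d", substr(sex, 1, 1), recs$rname,
                           seq_len(n)) else character(),
    flag = integer(n),
    rname = recs$rname,
    pos = recs$pos,
    mapq = rep(60L, n),
    cigar = rep(paste0(rl, "M"), n),
    qwidth = rep(rl, n),
    seq = if (n) recs$seq else character(),
    stringsAsFactors = FALSE)
  attr(aln, "contig_lengths") <- round(genome$spec$contigs)
  aln
}

# substitution errors: per-read error counts are binomial in read length,
# positions uniform, substituted base drawn from the other three
apply_substitutions <- function(seqs, error_rate) {
  if (length(seqs) == 0L || error_rate == 0) return(seqs)
  rl <- nchar(seqs)
  k <- rbinom(length(seqs), rl, error_rate)
  hit <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    at <- sample.int(rl[i], k[i])
    for (p in at) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seqs
}

#' Write simulator outputs to standard formats
#'
#' `write_genome_fasta()` writes the Y-inclusive reference (and optionally
#' the X haplotype) as FASTA; `write_truth_bed()` writes the planted
#' male-specific intervals as BED (0-based half-open).
#'
#' @param genome a `sex_genome`.
#' @param file output path.
#' @param which `"reference"` or `"x"`.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, file, which = c("reference", "x")) {
  which <- match.arg(which)
  Biostrings::writeXStringSet(
    if (which == "reference") genome$reference else genome$x_seq, file)
  invisible(file)
}

#' @rdname write_genome_fasta
#' @export
write_truth_bed <- function(genome, file) {
  rtracklayer::export(genome$truth_regions, file, format = "BED")
  invisible(file)
}
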