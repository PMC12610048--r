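#' Primer pair for marker validation
#'
#' @param name marker name.
#' @param forward,reverse primer sequences, 5'->3', over `{A,C,G,T}`,
#'   length at least 15.
#' @param expected_size expected product size in bp (metadata only).
#' @param tm annealing temperature in degrees C (metadata only).
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, expected_size = NA_integer_,
                        tm = NA_real_) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (s in c(forward, reverse)) {
    if (grepl("[^ACGT]", s)) stop_("primer contains non-ACGT symbols: %s", s)
    if (nchar(s) < 15) stop_("primer shorter than 15 nt: %s", s)
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 expected_size = expected_size, tm = tm),
            class = "primer_pair")
}

#' Read a primer table
#'
#' Tab-separated with header columns `name`, `forward`, `reverse` and
#' optionally `size` and `tm` (mirroring a published primer table).
#'
#' @param file path to the TSV.
#' @return a list of [primer_pair()] objects, named by marker.
#' @export
read_primer_table <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  pairs <- lapply(seq_len(nrow(df)), function(i) {
    primer_pair(df$name[i], df$forward[i], df$reverse[i],
                expected_size = if ("size" %in% names(df)) df$size[i] else NA,
                tm = if ("tm" %in% names(df)) df$tm[i] else NA)
  })
  setNames(pairs, df$name)
}

# match one primer on the plus strand of a template; returns an IRanges of
# accepted sites. anchor3 = "right": the primer's 3' end is the site's
# right edge (forward primer); "left": the 3' end maps to the site's left
# edge (the reverse primer matched as its reverse complement).
match_primer_sites <- function(template, primer, max_mismatch, anchor3) {
  pat <- Biostrings::DNAString(primer)
  hits <- Biostrings::matchPattern(pat, template, max.mismatch = max_mismatch)
  r <- IRanges::IRanges(Biostrings::start(hits), Biostrings::end(hits))
  if (length(r) == 0L || max_mismatch == 0L) return(r)
  # mismatch tolerance never extends to the 3 terminal 3' bases: on the
  # plus strand those are the last 3 bases of the forward pattern and the
  # first 3 of the reverse-complemented reverse pattern
  n <- nchar(primer)
  anchor <- if (anchor3 == "right") substr(primer, n - 2L, n)
            else substr(primer, 1L, 3L)
  ok <- vapply(seq_along(r), function(i) {
    site <- Biostrings::subseq(template, IRanges::start(r)[i], IRanges::end(r)[i])
    got <- if (anchor3 == "right")
      Biostrings::subseq(site, n - 2L, n) else Biostrings::subseq(site, 1L, 3L)
    as.character(got) == anchor
  }, logical(1))
  r[ok]
}

#' Predict PCR amplicons on one template
#'
#' Models conventional PCR without thermodynamics: the forward primer is
#' matched on the plus strand and the reverse primer's reverse complement
#' downstream on the plus strand; every pairing of a forward site with a
#' downstream reverse site whose product is at most `max_len` bp is
#' reported. Amplicon length includes both primer footprints. Up to
#' `max_mismatch` mismatches are tolerated per site, but the three
#' terminal 3' bases of each primer must match exactly (mispriming from a
#' mismatched 3' end does not extend).
#'
#' @param template a `DNAString`, single-sequence `DNAStringSet`, or
#'   character scalar.
#' @param pair a [primer_pair()].
#' @param max_len maximum product size in bp (default 5000, consistent
#'   with a 2-minute extension step).
#' @param max_mismatch mismatches tolerated per primer site (default 0).
#' @param template_id id recorded in the output (defaults to the sequence
#'   name, if any).
#' @return a data.frame with columns `template`, `start`, `end` (1-based
#'   inclusive template coordinates) and `length`, one row per amplicon,
#'   ordered by position.
#' @export
find_amplicons <- function(template, pair, max_len = 5000L, max_mismatch = 0L,
                           template_id = NULL) {
  stopifnot(inherits(pair, "primer_pair"))
  if (is(template, "DNAStringSet")) {
    stopifnot(length(template) == 1L)
    template_id <- template_id %||% names(template)
    template <- template[[1]]
  } else if (is.character(template)) {
    template <- Biostrings::DNAString(toupper(template))
  }
  template_id <- template_id %||% "template"
  if (length(template) == 0L) stop_("template is empty")

  fwd <- match_primer_sites(template, pair$forward, max_mismatch, "right")
  rev_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pair$reverse)))
  rev <- match_primer_sites(template, rev_rc, max_mismatch, "left")

  out <- data.frame(template = character(), start = integer(),
                    end = integer(), length = integer())
  if (length(fwd) && length(rev)) {
    grid <- expand.grid(f = seq_along(fwd), r = seq_along(rev))
    fs <- IRanges::start(fwd)[grid$f]
    re <- IRanges::end(rev)[grid$r]
    len <- re - fs + 1L
    ok <- IRanges::start(rev)[grid$r] > fs & len > 0L & len <= max_len
    if (any(ok)) {
      out <- data.frame(template = template_id, start = fs[ok], end = re[ok],
                        length = len[ok])
      out <- out[order(out$start, out$end), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

#' Collapse amplicon lengths into gel-distinguishable bands
#'
#' Lengths closer than `resolution` bp are reported as a single band (the
#' smallest length of the group is kept as the representative).
#'
#' @param lengths numeric vector of product lengths in bp.
#' @param resolution gel resolution tolerance in bp.
#' @return sorted numeric vector of distinct band lengths.
#' @export
collapse_bands <- function(lengths, resolution = 20) {
  lengths <- sort(unique(as.numeric(lengths)))
  if (length(lengths) <= 1L) return(lengths)
  keep <- lengths[1]
  for (x in lengths[-1]) if (x - keep[length(keep)] > resolution) keep <- c(keep, x)
  keep
}

#' Predict the gel band pattern of one genotype
#'
#' Runs [find_amplicons()] on each haplotype of a genotype (XX: two X
#' haplotypes; XY: one X and one Y-inclusive haplotype), pools the product
#' lengths, and collapses them into distinct bands at the given gel
#' resolution.
#'
#' @param haplotypes a `DNAStringSet` (or list/character vector) of one or
#'   two haplotype template sequences.
#' @param pair a [primer_pair()].
#' @param resolution gel resolution in bp (default 20, about what 1%
#'   agarose separates).
#' @param max_len,max_mismatch passed to [find_amplicons()].
#' @return an object of class `band_pattern`: list with sorted numeric
#'   `bands` and the `resolution` used.
#' @export
genotype_bands <- function(haplotypes, pair, resolution = 20, max_len = 5000L,
                           max_mismatch = 0L) {
  if (is(haplotypes, "DNAStringSet") || is.character(haplotypes))
    haplotypes <- as.list(haplotypes)
  stopifnot(length(haplotypes) >= 1L, length(haplotypes) <= 2L)
  lens <- unlist(lapply(haplotypes, function(h)
    find_amplicons(h, pair, max_len = max_len, max_mismatch = max_mismatch)$length))
  structure(list(bands = collapse_bands(lens %||% numeric(), resolution),
                 resolution = resolution),
            class = "band_pattern")
}

# does every band in `a` have a counterpart in `b` within `res` bp?
bands_subset <- function(a, b, res) {
  all(vapply(a, function(x) any(abs(b - x) <= res), logical(1)))
}

#' Classify a candidate marker from its per-sex band patterns
#'
#' A marker is sex-informative in an XX/XY system when males show every
#' female band plus at least one extra (Y-derived) band. Patterns are
#' compared at their gel resolution.
#'
#' @param male,female `band_pattern` objects from [genotype_bands()],
#'   computed at equal resolution.
#' @return one of `"male_extra_band"`, `"uninformative"`,
#'   `"no_amplification"`, `"ambiguous"`.
#' @export
classify_marker <- function(male, female) {
  stopifnot(inherits(male, "band_pattern"), inherits(female, "band_pattern"))
  if (male$resolution != female$resolution)
    stop_("band patterns were computed at different resolutions")
  res <- male$resolution
  m <- male$bands; f <- female$bands
  if (length(m) == 0L && length(f) == 0L) return("no_amplification")
  eq <- length(m) == length(f) && bands_subset(m, f, res) && bands_subset(f, m, res)
  if (eq) return("uninformative")
  if (length(f) > 0L && length(m) > length(f) && bands_subset(f, m, res))
    return("male_extra_band")
  "ambiguous"
}

#' @export
print.band_pattern <- function(x, ...) {
  cat(sprintf("band pattern: {%s} bp (resolution %g bp)\n",
              paste(x$bands, collapse = ", "), x$resolution))
  invisible(x)
}
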