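#' The Mar28 sex-marker primer pair
#'
#' The validated chromosome-8 marker: in XY males it amplifies two bands
#' (509 and 814 bp), in XX females a single 509-bp band, because the Y
#' haplotype carries a 305-bp insertion between the primer sites.
#'
#' @return a [primer_pair()].
#' @export
mar28_primers <- function() {
  primer_pair("Mar28",
              forward = "AGTGATTCAGATTGGATGGACTGA",
              reverse = "AACACTATATCCTGCACCGGATT",
              expected_size = 509L, tm = 56)
}

#' Build X and Y haplotype templates for an insertion-junction marker
#'
#' Constructs the locus structure behind a junction-spanning sex marker:
#' shared flanking sequence containing both primer sites, an X-haplotype
#' amplicon of `amplicon_x` bp, and a Y haplotype identical except for a
#' male-specific insertion of `insert_length` bp placed strictly between
#' the two primer sites. The Y amplicon is therefore
#' `amplicon_x + insert_length` bp. Filler sequence is random at the given
#' seed; construction verifies that each haplotype yields exactly one
#' amplicon (no spurious primer sites) and advances the stream until that
#' holds, so the result is deterministic per seed.
#'
#' Defaults reproduce the Mar28 locus: a 509-bp X product and a 305-bp
#' Y-specific insertion, giving the 509/814 male band pair.
#'
#' @param pair a [primer_pair()]; default [mar28_primers()].
#' @param amplicon_x X-haplotype product size in bp (primers included).
#' @param insert_length Y-specific insertion length in bp.
#' @param flank bp of template sequence outside each primer site.
#' @param seed integer seed for the filler sequence.
#' @return list with `templates` (a `DNAStringSet` named `X` and `Y`),
#'   `pair`, `amplicon_x` and `insert_length`.
#' @examples
#' fx <- marker_fixture()
#' find_amplicons(fx$templates[["Y"]], fx$pair)$length  # 814
#' @export
marker_fixture <- function(pair = mar28_primers(), amplicon_x = 509L,
                           insert_length = 305L, flank = 200L, seed = 101L) {
  nf <- nchar(pair$forward); nr <- nchar(pair$reverse)
  inner <- as.integer(amplicon_x) - nf - nr
  if (inner < 2L) stop_("amplicon_x too small for the primer footprints")
  rc_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pair$reverse)))
  left_inner <- inner %/% 2L
  with_seed(seed, {
    for (attempt in 1:50) {
      up <- random_dna(flank, 0.4)
      dn <- random_dna(flank, 0.4)
      mid <- random_dna(inner, 0.4)
      ins <- random_dna(insert_length, 0.4)
      x_tpl <- paste0(up, pair$forward, mid, rc_rev, dn)
      y_tpl <- paste0(up, pair$forward, substr(mid, 1L, left_inner), ins,
                      substr(mid, left_inner + 1L, inner), rc_rev, dn)
      ax <- find_amplicons(x_tpl, pair, max_len = 10000L)
      ay <- find_amplicons(y_tpl, pair, max_len = 10000L)
      if (nrow(ax) == 1L && nrow(ay) == 1L &&
          ax$length == amplicon_x &&
          ay$length == amplicon_x + insert_length) break
    }
    templates <- Biostrings::DNAStringSet(c(X = x_tpl, Y = y_tpl))
    list(templates = templates, pair = pair,
         amplicon_x = as.integer(amplicon_x),
         insert_length = as.integer(insert_length))
  })
}

#' In-silico validation of an insertion-junction marker
#'
#' Predicts the male (XY: one X and one Y haplotype) and female (XX: two X
#' haplotypes) band patterns for a marker fixture and classifies the
#' marker.
#'
#' @param fixture a [marker_fixture()].
#' @param resolution gel resolution in bp.
#' @param max_mismatch mismatches tolerated per primer site.
#' @return list with `male` and `female` `band_pattern`s and `call`, the
#'   [classify_marker()] result.
#' @export
validate_marker <- function(fixture = marker_fixture(), resolution = 20,
                            max_mismatch = 0L) {
  tpl <- fixture$templates
  male <- genotype_bands(tpl[c("X", "Y")], fixture$pair,
                         resolution = resolution, max_mismatch = max_mismatch)
  female <- genotype_bands(tpl[c("X", "X")], fixture$pair,
                           resolution = resolution, max_mismatch = max_mismatch)
  list(male = male, female = female, call = classify_marker(male, female))
}
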