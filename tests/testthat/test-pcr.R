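# independent amplicon oracle: exact substring scan with base R
scan_amplicons <- function(template, fwd, rev, max_len) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  f_at <- gregexpr(fwd, template, fixed = TRUE)[[1]]
  r_at <- gregexpr(rc(rev), template, fixed = TRUE)[[1]]
  f_at <- f_at[f_at > 0]; r_at <- r_at[r_at > 0]
  out <- integer()
  for (fs in f_at) for (rs in r_at) {
    re <- rs + nchar(rev) - 1L
    len <- re - fs + 1L
    if (rs > fs && len > 0 && len <= max_len) out <- c(out, len)
  }
  sort(out)
}

test_that("marker fixture haplotypes yield the expected X and Y products", {
  fx <- marker_fixture()
  ax <- find_amplicons(fx$templates[["X"]], fx$pair)
  ay <- find_amplicons(fx$templates[["Y"]], fx$pair)
  expect_identical(nrow(ax), 1L)
  expect_identical(nrow(ay), 1L)
  expect_identical(ax$length, 509L)
  expect_identical(ay$length, 814L)
  # amplicon length includes both primer footprints
  expect_identical(ax$end - ax$start + 1L, ax$length)
})

test_that("templates lacking a primer site yield no amplicons", {
  pair <- mar28_primers()
  expect_identical(nrow(find_amplicons(strrep("ACGT", 100), pair)), 0L)
  # forward site only
  tpl <- paste0(strrep("AC", 50), pair$forward, strrep("GT", 50))
  expect_identical(nrow(find_amplicons(tpl, pair)), 0L)
  expect_error(primer_pair("bad", "ACGTNACGTACGTACGT", "ACGTACGTACGTACG"),
               "non-ACGT")
  expect_error(primer_pair("short", "ACGTACGT", "ACGTACGTACGTACG"), "15")
})

test_that("exact-match amplicon search equals a brute-force substring scan", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  for (i in 1:25) {
    fwd <- paste(sample(bases, 18, replace = TRUE), collapse = "")
    rev <- paste(sample(bases, 17, replace = TRUE), collapse = "")
    pair <- primer_pair("p", fwd, rev)
    rc_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
    # paste several primer sites into a random backbone, some nested
    chunks <- c(paste(sample(bases, 200, replace = TRUE), collapse = ""),
                sample(c(fwd, rc_rev,
                         paste(sample(bases, 150, replace = TRUE), collapse = "")),
                       sample(3:6, 1), replace = TRUE),
                paste(sample(bases, 200, replace = TRUE), collapse = ""))
    tpl <- paste(chunks, collapse = "")
    max_len <- sample(c(300L, 1000L, 5000L), 1)
    got <- sort(find_amplicons(tpl, pair, max_len = max_len)$length)
    expect_identical(got, scan_amplicons(tpl, fwd, rev, max_len))
  }
})

test_that("reverse-complementing the template and swapping primers preserves lengths", {
  set.seed(5)
  for (i in 1:10) {
    fx <- marker_fixture(insert_length = sample(50:500, 1),
                         seed = 1000L + i)
    tpl <- fx$templates[["Y"]]
    pair <- fx$pair
    flipped <- Biostrings::reverseComplement(tpl)
    swapped <- primer_pair(pair$name, pair$reverse, pair$forward)
    a <- find_amplicons(tpl, pair)
    b <- find_amplicons(flipped, swapped)
    expect_identical(sort(a$length), sort(b$length))
  }
})

test_that("mismatch tolerance spares the 3' anchor", {
  pair <- primer_pair("p", "ACGTACGTACGTACGTAC", "TTGCAATTGGCCAATTGG")
  rc_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pair$reverse)))
  backbone <- function(f_site, r_site)
    paste0(strrep("CA", 30), f_site, strrep("TG", 40), r_site, strrep("AC", 30))

  # internal mismatch in the forward site: missed exactly, found with tolerance
  f_mut <- pair$forward
  substr(f_mut, 5, 5) <- "T"   # was A
  tpl <- backbone(f_mut, rc_rev)
  expect_identical(nrow(find_amplicons(tpl, pair, max_mismatch = 0)), 0L)
  expect_identical(nrow(find_amplicons(tpl, pair, max_mismatch = 1)), 1L)

  # mismatch in the forward primer's 3' terminal bases: never tolerated
  f_end <- pair$forward
  substr(f_end, 18, 18) <- "G" # was C
  tpl2 <- backbone(f_end, rc_rev)
  expect_identical(nrow(find_amplicons(tpl2, pair, max_mismatch = 2)), 0L)

  # mismatch at the reverse primer's 3' end = start of its plus-strand site
  r_end <- rc_rev
  substr(r_end, 1, 1) <- "G"   # was C
  tpl3 <- backbone(pair$forward, r_end)
  expect_identical(nrow(find_amplicons(tpl3, pair, max_mismatch = 2)), 0L)
  # the same site with an internal mismatch is tolerated
  r_mid <- rc_rev
  substr(r_mid, 9, 9) <- "A"   # was G
  tpl4 <- backbone(pair$forward, r_mid)
  expect_identical(nrow(find_amplicons(tpl4, pair, max_mismatch = 1)), 1L)
})

test_that("bands collapse at gel resolution and markers classify correctly", {
  expect_identical(collapse_bands(c(509, 514), resolution = 20), 509)
  expect_identical(collapse_bands(c(509, 814), resolution = 20), c(509, 814))
  expect_identical(collapse_bands(numeric()), numeric())

  bp <- function(bands) structure(list(bands = bands, resolution = 20),
                                  class = "band_pattern")
  expect_identical(classify_marker(bp(c(509, 814)), bp(509)), "male_extra_band")
  expect_identical(classify_marker(bp(509), bp(509)), "uninformative")
  expect_identical(classify_marker(bp(numeric()), bp(numeric())),
                   "no_amplification")
  # female-only band is not a usable male marker
  expect_identical(classify_marker(bp(509), bp(c(509, 700))), "ambiguous")
  expect_identical(classify_marker(bp(700), bp(509)), "ambiguous")
  # near-equal bands compare at resolution
  expect_identical(classify_marker(bp(c(509, 814)), bp(512)), "male_extra_band")
  expect_error(classify_marker(bp(509),
                               structure(list(bands = 509, resolution = 5),
                                         class = "band_pattern")),
               "resolution")
})

test_that("primer tables round-trip through TSV", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("name\tforward\treverse\tsize\ttm",
               paste("Mar28", mar28_primers()$forward, mar28_primers()$reverse,
                     509, 56, sep = "\t")), f)
  pairs <- read_primer_table(f)
  expect_named(pairs, "Mar28")
  expect_identical(pairs$Mar28$forward, mar28_primers()$forward)
  expect_identical(pairs$Mar28$expected_size, 509L)
})
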