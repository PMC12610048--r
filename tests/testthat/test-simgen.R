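test_that("a genome with no insertions is its own X haplotype", {
  g <- build_genome(sex_genome_spec(c(chr1 = 5000, chr2 = 2000), base_seed = 3))
  expect_identical(as.character(g$x_seq), as.character(g$reference))
  expect_length(g$truth_regions, 0)
})

test_that("single-edit bookkeeping: X length and exact liftover", {
  # one 100-kb contig, a 305-bp insertion occupying reference bases
  # 50,001..50,305 (i.e. starting after the 50,000th base)
  g <- build_genome(sex_genome_spec(
    c(chr1 = 100000),
    data.frame(contig = "chr1", start = 50001, length = 305),
    base_seed = 42))
  expect_identical(unname(g$x_lengths), 99695L)
  expect_identical(lift_ref_to_x(g, "chr1", 50306), 50001L)
  expect_identical(lift_ref_to_x(g, "chr1", 50000), 50000L)
  expect_identical(lift_x_to_ref(g, "chr1", 50001), 50306L)
  # positions inside the insertion have no X image
  expect_true(all(is.na(lift_ref_to_x(g, "chr1", 50001:50305))))
  # the X sequence really is the reference with the interval excised
  ref <- as.character(g$reference[[1]])
  expect_identical(as.character(g$x_seq[[1]]),
                   paste0(substr(ref, 1, 50000), substr(ref, 50306, 100000)))
})

test_that("liftover is a bijection on unedited positions", {
  for (seed in 1:3) {
    spec <- with(list(), {
      set.seed(seed * 17)
      starts <- sort(sample(seq(1000, 90000, by = 2500), 4))
      sex_genome_spec(c(chrA = 100000),
                      data.frame(contig = "chrA", start = starts,
                                 length = sample(50:400, 4)),
                      base_seed = seed)
    })
    g <- build_genome(spec)
    set.seed(seed)
    ref_pos <- sample.int(100000, 500)
    x <- lift_ref_to_x(g, "chrA", ref_pos)
    edited <- is.na(x)
    expect_identical(lift_x_to_ref(g, "chrA", x[!edited]), ref_pos[!edited])
    # and the reverse direction over the whole X range
    x_pos <- sample.int(g$x_lengths[["chrA"]], 500)
    r <- lift_x_to_ref(g, "chrA", x_pos)
    expect_identical(lift_ref_to_x(g, "chrA", r), x_pos)
  }
})

test_that("invalid insertion lists are rejected with the offending interval", {
  expect_error(sex_genome_spec(c(chr1 = 1000),
                               data.frame(contig = "chr1", start = 900,
                                          length = 200)),
               "not strictly inside")
  expect_error(sex_genome_spec(c(chr1 = 1000),
                               data.frame(contig = "chr1", start = c(100, 150),
                                          length = c(100, 50))),
               "overlapping")
  expect_error(sex_genome_spec(c(chr1 = 1000),
                               data.frame(contig = "chr2", start = 100,
                                          length = 50)),
               "unknown contig")
  expect_error(sex_genome_spec(c(chr1 = 1000),
                               data.frame(contig = "chr1", start = 100,
                                          length = 0)),
               "positive")
})

test_that("female pool never covers insertion interiors; male does at half depth", {
  g <- build_genome(sex_genome_spec(
    c(chr1 = 100000),
    data.frame(contig = "chr1", start = 50001, length = 2000),
    base_seed = 11))
  pm <- read_sim_params(depth = 20, seed = 101)
  pf <- read_sim_params(depth = 20, seed = 102)
  male <- simulate_pool(g, "male", pm)
  female <- simulate_pool(g, "female", pf)

  # no female read can start strictly inside the insertion
  inside_f <- female$pos >= 50001 & female$pos <= 52000
  expect_identical(sum(inside_f), 0L)

  # male insertion-interior coverage ~ depth/2 (only the Y-inclusive
  # haplotype contributes); count read starts over the interior windows
  core <- male$pos >= 50001 & male$pos <= 52000 - pm$read_length
  lambda <- (pm$depth / 2) * (2000 - pm$read_length) / pm$read_length
  expect_lt(abs(sum(core) - lambda), 4 * sqrt(lambda))

  # total female read count within 4 sd of depth * hap_len / read_length
  exp_n <- pf$depth * g$x_lengths[["chr1"]] / pf$read_length
  expect_lt(abs(nrow(female) - exp_n), 4 * sqrt(exp_n))

  # records are coordinate-sorted
  expect_false(is.unsorted(male$pos))
  expect_false(is.unsorted(female$pos))
})

test_that("depth zero yields an empty record stream", {
  g <- build_genome(sex_genome_spec(c(chr1 = 10000), base_seed = 1))
  expect_identical(nrow(simulate_pool(g, "male",
                                      read_sim_params(0, seed = 1))), 0L)
})

test_that("simulation is deterministic and SAM output byte-identical per seed", {
  g <- build_genome(sex_genome_spec(
    c(chr1 = 20000),
    data.frame(contig = "chr1", start = 10001, length = 400), base_seed = 5))
  p <- read_sim_params(depth = 6, error_rate = 0.01, seed = 99)
  a <- simulate_pool(g, "male", p)
  b <- simulate_pool(g, "male", p)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(a, f1); write_sam(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different read set
  expect_false(identical(a$pos,
                         simulate_pool(g, "male",
                                       read_sim_params(6, error_rate = 0.01,
                                                       seed = 100))$pos))
})

test_that("SAM round-trip through Rsamtools preserves the record table", {
  g <- build_genome(sex_genome_spec(c(chr1 = 8000), base_seed = 2))
  a <- simulate_pool(g, "female", read_sim_params(4, seed = 13))
  f <- tempfile(fileext = ".sam")
  write_sam(a, f)
  back <- read_alignments(f)
  expect_identical(back$pos, a$pos)
  expect_identical(back$qname, a$qname)
  expect_identical(back$seq, a$seq)
  expect_identical(attr(back, "contig_lengths"), c(chr1 = 8000L))
})
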