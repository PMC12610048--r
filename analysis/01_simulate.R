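#!/usr/bin/env Rscript

# Stage 1: build the synthetic study system and the two pooled read sets.
#
# One 500-kb contig carries a single 3-kb Y-specific insertion at its
# midpoint; the reference is male-derived (Y-inclusive), so the insertion
# is present in the reference and the X haplotype lacks it. The male pool
# (20x) draws half its depth from the X haplotype and half from the
# Y-inclusive haplotype; the female pool (26x) draws from two X
# haplotypes and therefore never covers the insertion. Pools are written
# as coordinate-sorted SAM, the truth interval as BED.

suppressMessages(library(cqscreen))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- sex_genome_spec(
  contigs = c(chr1 = 500000),
  insertions = data.frame(contig = "chr1", start = 250001L, length = 3000L),
  base_seed = 7L)
genome <- build_genome(spec)

male <- simulate_pool(genome, "male", read_sim_params(depth = 20, seed = 70L))
female <- simulate_pool(genome, "female",
                        read_sim_params(depth = 26, seed = 71L))

write_genome_fasta(genome, file.path(out, "reference.fasta"))
write_truth_bed(genome, file.path(out, "truth_regions.bed"))
write_sam(male, file.path(out, "male_pool.sam"))
write_sam(female, file.path(out, "female_pool.sam"))

cat(sprintf("reference: %d bp, X haplotype: %d bp\n",
            sum(Biostrings::width(genome$reference)), sum(genome$x_lengths)))
cat(sprintf("male pool: %d reads (~%.1fx), female pool: %d reads (~%.1fx)\n",
            nrow(male), nrow(male) * 150 / 5e5,
            nrow(female), nrow(female) * 150 / 5e5))
cat(sprintf("truth region: chr1:%d-%d\n",
            GenomicRanges::start(genome$truth_regions),
            GenomicRanges::end(genome$truth_regions)))
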