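#!/usr/bin/env Rscript

# Stage 3: extract each candidate region with 1 kb of flanking sequence on
# both sides, the input a primer-design tool needs.

suppressMessages(library(cqscreen))

regions <- rtracklayer::import("results/screen/regions.bed")
flanks <- extract_flanks(regions, "results/sim/reference.fasta",
                         flank = 1000L)
Biostrings::writeXStringSet(flanks, "results/screen/region_flanks.fasta")

for (i in seq_along(flanks))
  cat(sprintf("%s: %d bp (region %d bp + flanks)\n", names(flanks)[i],
              Biostrings::width(flanks)[i], GenomicRanges::width(regions)[i]))
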