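Package: cqscreen
Title: Chromosome-Quotient Screening for Sex-Specific Marker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery and in-silico validation of PCR-based sex markers from
    pooled (bulked-segregant) resequencing of an XX/XY genome. Simulates a
    male-derived reference carrying Y-specific insertions together with
    coordinate-sorted male and female pool alignments, tiles the reference
    into windows and counts filtered reads per pool, computes the per-window
    chromosome quotient CQ = Hf/Hm and applies hard retention thresholds,
    merges retained windows into candidate male-specific regions, extracts
    flanking sequence for primer design, and predicts per-genotype PCR band
    patterns to classify markers as sex-informative.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
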