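---
title: "Chromosome-quotient screening for male-specific regions and PCR sex markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-quotient screening for male-specific regions and PCR sex markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqscreen)
```

## The problem and the model

In a male-heterogametic (XX/XY) species, sequence that exists only on the Y
haplotype is covered by reads from a male DNA pool but not from a female
pool. Pooled (bulked-segregant) resequencing of the two sexes against a
male-derived reference therefore turns "Y-specific" into a simple coverage
contrast. The screen statistic is the **chromosome quotient**,

$$\mathrm{CQ} = \frac{H_f}{H_m},$$

computed per genomic window, where $H_m$ and $H_f$ are the numbers of
male-pool and female-pool reads assigned to the window. Autosomal and
X-shared sequence attracts reads from both pools in proportion to pool
depth, so CQ sits near the depth ratio; sequence present only on the Y
receives male reads but essentially no female reads, so CQ collapses toward
zero. Windows with

$$\mathrm{CQ} < 0.2 \quad\text{and}\quad H_m > 30$$

(both inequalities strict) are retained as candidate male-specific windows,
merged into regions, and each region is extracted with 1 kb of flanking
sequence as the substrate for primer design. A designed marker is finally
checked *in silico*: PCR products are predicted per haplotype, pooled into
per-genotype band patterns, and a marker is called sex-informative when the
male pattern contains every female band plus at least one extra,
Y-derived band.

The package implements this workflow end to end on synthetic data: a
generator for XY genomes with planted Y-specific insertions and pooled,
pre-aligned reads; windowed counting from SAM/BAM; the CQ screen; region
merging and flank extraction; and in-silico PCR with band-pattern
classification. The `analysis/` scripts run the stages as a narrative
workflow; every computation lives in package functions so tests can
exercise each stage in isolation.

## Why the reference must be Y-inclusive

The screen only works if male-specific sequence is *present* in the
reference: females then fail to cover it. The simulator therefore treats
the assembly as male-derived. A genome is specified as contigs plus a list
of insertion intervals (`sex_genome_spec()`); `build_genome()` keeps the
insertions in the reference, records them as ground-truth regions, and
derives the X haplotype by excising them, with an exact coordinate
liftover between the two systems. Within the validated marker's locus the
same structure appears in miniature: the Y haplotype carries a 305-bp
insertion between two primer sites, so the X product is 509 bp and the Y
product 814 bp. A printed marker interval of 509 bp is consistent with the
reference carrying the X-like allele at that locus, while the screen
requires female dropout, i.e. a Y-inclusive reference; the published
account does not say which allele its assembly carries, and we model the
Y-inclusive reading throughout because it is the only one under which the
screen finds insertion loci. The tension is noted here rather than
resolved.

## The simulator and what it does (not) emulate

`simulate_pool()` emulates sequencing plus alignment jointly, emitting
already-aligned, coordinate-sorted records:

* **Female (XX)**: reads sampled from two X haplotypes, each at half the
  pool depth. By construction no female read can start inside an insertion
  interior — this is a bookkeeping guarantee, not a statistical tendency,
  and the tests assert it exactly.
* **Male (XY)**: one X haplotype and one Y-inclusive (reference)
  haplotype, each at half depth. Insertion interiors thus see roughly half
  the male pool depth.
* Read starts are uniform; read counts per haplotype are Poisson with mean
  `depth/2 × haplotype_length / read_length`.
* X-derived reads that would span an excision junction are **dropped**
  rather than soft-clipped. This keeps every emitted record ungapped and
  the counting contract trivial, at the cost of a small coverage dip
  within a read length of each junction.
* Errors are substitution-only at a fixed per-base rate; default
  `error_rate = 0.001`, a Q30-grade error level consistent with the >95%
  Q30 typical of the pooled libraries this emulates. Defaults
  `read_length = 150` and the study depths (about 20–30×) reflect the same
  setting.
* Every stochastic step takes a mandatory explicit integer seed, and
  identical spec + seed gives byte-identical output files.

Real pools differ in ways the simulator deliberately ignores: X/Y
divergence outside the planted insertions (SNVs, small indels), paired-end
structure, mapping-quality pathology in repeats, PCR duplicates and GC
bias. Passing tests therefore demonstrate the *screen logic* — counting,
thresholding, merging, liftover bookkeeping — on an idealized signal, not
robustness to alignment artifacts in real data.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `window` | 500 bp | window size of the published screen |
| `step` | 1000 bp | published step; note it exceeds the window, leaving 500-bp gaps (warned at run time) |
| `cq_max` | 0.2 | retain windows with CQ strictly below this |
| `hm_min` | 30 | retain windows with Hm strictly above this; guards against calling CQ on noise-level counts |
| `merge_gap` | 0 bp | retained windows overlapping or bookended are unioned |
| `normalize_depth` | off | optionally rescales Hf by the pool-total ratio before division |
| `min_mapq` | 0 | no MAPQ cut; duplicates/secondary/supplementary/unmapped excluded |
| `flank` | 1000 bp | flanking sequence extracted per region for primer design |
| gel `resolution` | 20 bp | bands closer than this are reported as one (≈1% agarose) |
| `max_len` | 5000 bp | longest considered PCR product (≈2-min extension) |

Three of these deserve comment.

**Step versus window.** The published parameters (window 500, step 1000)
cannot produce overlapping windows, yet the published procedure merges
"overlapping" windows. We surface this contradiction instead of silently
fixing it: `make_windows()` warns when `step > window`, the default
`merge_gap = 0` implements the literal "overlapping or bookended" rule, and
the documented recipe for the literal parameterization sets
`merge_gap = 500` so retained tiles separated by the tiling gap coalesce.
The end-to-end analysis here uses a denser step (100 bp) so that the
planted-region recovery property is sharp; a transposed window/step in the
original description would have the same effect.

**Counting mode.** "Number of reads in a window" is ambiguous. The default
assigns a read to every window containing its *leftmost aligned position*:
in a non-overlapping tiling each read is counted exactly once, giving a
conservation law (counts sum to filtered reads) and a clean brute-force
oracle. An `overlap` mode is provided for sensitivity analysis.

**Depth normalization.** With unequal pool depths (the emulated study
sequenced the female pool ~30% deeper), raw CQ centers on the depth ratio
rather than 1. The published screen describes no correction, so
`normalize_depth` defaults to off; for male-specific discovery the bias is
conservative (it inflates CQ, never deflates it below the threshold).
The per-window output keeps the raw integer pair `(Hf, Hm)` next to the
decimal CQ so threshold decisions are reproducible exactly.

## Numerical and convention choices

* **Coordinates.** Internally everything is 1-based inclusive, the native
  convention of `IRanges`/`GenomicRanges` on which the interval machinery
  is built; BED writers convert to 0-based half-open. Published sizes mix
  two conventions — a half-open span (a 1032-bp region printed from
  end − start) and a 1-based inclusive size (a 509-bp interval printed
  from end − start + 1) — so `region_length()` implements both explicitly.
* **Strictness.** Both retention thresholds are strict inequalities, read
  verbatim: CQ = 0.2 and Hm = 30 are rejected. Tests pin this at the exact
  boundary using integer count pairs (e.g. Hf = 7, Hm = 35).
* **Undefined CQ.** Hm = 0 leaves CQ undefined (`NA`) and the window is
  never retained, regardless of Hf.
* **In-silico PCR.** Primer sites are matched exactly by default. With
  mismatch tolerance enabled, the three terminal 3′ bases of each primer
  must still match exactly — a mismatched 3′ end does not extend — which
  is the standard reason a junction marker survives the point
  polymorphisms seen across populations while remaining locus-specific.
  No thermodynamics is modeled; products are reported purely from site
  geometry, with length including both primer footprints.
* **Band collapse.** Product lengths are collapsed greedily in ascending
  order; lengths within `resolution` of the last kept band merge into it.
  Classification compares band patterns at the same resolution.
* **Degenerate inputs.** Depth 0 yields an empty, valid record stream;
  empty alignment streams count to all-zero windows; merging an empty
  retained set yields no regions; flank extraction clamps at contig ends.

## Problem sizes

The synthetic study system is a single 500-kb contig with one 3-kb planted
insertion, male pool 20× and female pool 26×, screened at window 500 /
step 100. At these sizes the full pipeline — genome, ~150k reads across
both pools, 5000 windows, screening and merging — runs in a few seconds,
and the suite's property checks (200 random counting instances against a
brute-force oracle, 100 random insertion lengths for junction additivity)
complete comfortably within a normal test run. These sizes were chosen as
the smallest at which the recovery property is unambiguous: the insertion
spans many windows, interior Hm sits well above the retention threshold at
half depth, and the null genome has no window within reach of CQ < 0.2.

On that system the screen recovers the planted insertion with sensitivity
and precision 1.0 and reports nothing on a null genome, and the in-silico
validation of the reconstructed marker locus reproduces the published band
patterns — male {509, 814}, female {509}, call `male_extra_band` — as the
test suite and `scripts/acceptance.R` verify by recomputation.

## Known limitations

* The screen detects *presence/absence* contrast only; Y-specific SNV
  divergence without coverage dropout is invisible to CQ on a male-derived
  reference at these settings.
* Sensitivity/precision statements are at region granularity (overlap with
  truth), not base-pair boundary accuracy; retained edge windows can
  extend a region up to a window length beyond the true insertion.
* The in-silico PCR models site geometry, not amplification efficiency;
  markers flagged `male_extra_band` here can still fail in the lab for
  thermodynamic reasons, which is why the emulated study screened dozens
  of primer pairs to validate one.
* The simulator's idealizations listed above mean real-data performance
  claims require real alignments; the package reads standard
  coordinate-sorted SAM/BAM, so the same screen applies unchanged.
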