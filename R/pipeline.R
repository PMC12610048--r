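#' Run the full screen: simulate, count, screen, merge, extract flanks
#'
#' Orchestrates the pipeline end to end on a synthetic XY genome:
#' builds the genome, simulates the two sex pools, tiles windows, counts
#' filtered reads per pool, computes the chromosome quotient, retains and
#' merges candidate windows, extracts flanks, and evaluates the reported
#' regions against the planted truth intervals. Sensitivity is the
#' fraction of truth intervals overlapped by at least one reported region;
#' precision is the fraction of reported regions overlapping truth.
#'
#' @param genome_spec a [sex_genome_spec()] (or a prebuilt `sex_genome`).
#' @param male_params,female_params [read_sim_params()] per pool.
#' @param config a [screen_config()].
#' @param filters a [count_filters()].
#' @param flank bp of flanking sequence extracted per region.
#' @param out_dir optional directory; when given, all artifacts are
#'   written there (reference FASTA, pool SAMs, truth and region BED,
#'   count/screen/region TSVs, flank FASTA, manifest).
#' @return list with `genome`, `windows`, `male_counts`, `female_counts`,
#'   `cq`, `retained`, `regions`, `flanks`, `sensitivity`, `precision`
#'   and `manifest`. Sensitivity is `NA` when no truth regions were
#'   planted; precision is `NA` when no regions were reported.
#' @export
run_sex_screen <- function(genome_spec, male_params, female_params,
                           config = screen_config(), filters = count_filters(),
                           flank = 1000L, out_dir = NULL) {
  genome <- if (inherits(genome_spec, "sex_genome")) genome_spec
            else build_genome(genome_spec)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  male <- stage("simulate_male", simulate_pool(genome, "male", male_params))
  female <- stage("simulate_female",
                  simulate_pool(genome, "female", female_params))
  windows <- stage("windows",
                   make_windows(round(genome$spec$contigs),
                                window = config$window, step = config$step))
  mc <- stage("count_male", count_reads(male, windows, filters))
  fc <- stage("count_female", count_reads(female, windows, filters))
  cq <- stage("cq", compute_cq(mc, fc, config))
  retained <- stage("select", select_windows(cq, config))
  regions <- stage("merge", merge_windows(retained, config$merge_gap))
  flanks <- stage("flanks",
                  extract_flanks(regions, genome$reference, flank = flank))

  truth <- genome$truth_regions
  sensitivity <- if (length(truth) == 0L) NA_real_ else
    mean(GenomicRanges::countOverlaps(truth, regions) > 0L)
  precision <- if (length(regions) == 0L) NA_real_ else
    mean(GenomicRanges::countOverlaps(regions, truth) > 0L)

  manifest <- list(
    package_version = as.character(packageVersion("cqscreen")),
    genome_spec = genome$spec,
    male_params = male_params, female_params = female_params,
    config = config, filters = filters, flank = as.integer(flank),
    n_reads = c(male = nrow(male), female = nrow(female)),
    n_windows = length(windows), n_retained = length(retained),
    n_regions = length(regions),
    sensitivity = sensitivity, precision = precision)

  res <- list(genome = genome, male = male, female = female,
              windows = windows, male_counts = mc, female_counts = fc,
              cq = cq, retained = retained, regions = regions,
              flanks = flanks, sensitivity = sensitivity,
              precision = precision, manifest = manifest)
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' Re-run a screen from its manifest
#'
#' The manifest snapshots every input (genome spec, simulation parameters,
#' screen configuration, seeds), so re-running reproduces the original
#' outputs exactly.
#'
#' @param manifest the `manifest` element of a [run_sex_screen()] result.
#' @param out_dir optional output directory, as in [run_sex_screen()].
#' @return a [run_sex_screen()] result list.
#' @export
rerun_from_manifest <- function(manifest, out_dir = NULL) {
  run_sex_screen(manifest$genome_spec, manifest$male_params,
                 manifest$female_params, config = manifest$config,
                 filters = manifest$filters, flank = manifest$flank,
                 out_dir = out_dir)
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_genome_fasta(res$genome, p("reference.fasta"))
  write_truth_bed(res$genome, p("truth_regions.bed"))
  write_sam(res$male, p("male_pool.sam"))
  write_sam(res$female, p("female_pool.sam"))
  write_counts_tsv(res$male_counts, p("male_counts.tsv"))
  write_counts_tsv(res$female_counts, p("female_counts.tsv"))
  write_screen_tsv(res$cq, p("cq_windows.tsv"))
  write_regions_bed(res$regions, p("regions.bed"))
  write_regions_tsv(res$regions, p("regions.tsv"))
  if (length(res$flanks))
    Biostrings::writeXStringSet(res$flanks, p("region_flanks.fasta"))
  write_manifest(res$manifest, p("manifest.txt"))
  invisible(out_dir)
}

# plain-text key: value snapshot of the run
write_manifest <- function(manifest, file) {
  fmt <- function(x) {
    out <- if (is.list(x)) paste(sprintf("%s=%s", names(x),
                                         vapply(x, fmt, "")), collapse = "; ")
           else paste(format(x), collapse = ",")
    # explicit sequences are summarized, not dumped
    if (nchar(out) > 200) out <- paste0(substr(out, 1, 197), "...")
    out
  }
  lines <- sprintf("%s: %s", names(manifest), vapply(manifest, fmt, ""))
  writeLines(lines, file)
  invisible(file)
}
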