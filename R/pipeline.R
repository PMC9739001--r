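#' Default analysis thresholds
#'
#' All pipeline thresholds in one place: population-frequency cutoff
#' 0.1%, VAF cutoff 5%, TMB-high cutoff 10 mut/Mb, amplification ratio 3,
#' minimum tumor purity 0.30, splice flank 2 bp.
#'
#' @param ... Overrides.
#' @return Named list of thresholds.
#' @export
run_config <- function(...) {
  cfg <- list(pop_af_threshold = 0.001, vaf_threshold = 0.05,
              tmb_high_cutoff = 10, amp_ratio_threshold = 3,
              min_purity = 0.30, splice_flank_bp = 2,
              min_signature_mutations = 20)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (any(unlist(cfg) <= 0)) stop("thresholds must be positive")
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML path.
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname load_run_config
#' @param cfg A [run_config()] list.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.sim_files <- function(dir) {
  list(vcf = file.path(dir, "cohort.vcf"),
       coverage = file.path(dir, "coverage.tsv"),
       densities = file.path(dir, "densities.tsv"),
       metadata = file.path(dir, "metadata.tsv"),
       truth = file.path(dir, "ground_truth.json"),
       fasta = file.path(dir, "reference.fasta"),
       panel_bed = file.path(dir, "panel.bed"),
       panel_yaml = file.path(dir, "panel.yaml"),
       signatures = file.path(dir, "signatures.tsv"))
}

#' Simulate a complete synthetic study to disk
#'
#' Writes a full synthetic study into `dir`: reference FASTA, panel BED +
#' YAML (splice flank and TERT promoter), multi-sample VCF, coverage TSV,
#' density TSV, metadata TSV (both study arms), signature TSV, and the
#' ground-truth JSON. Deterministic for a fixed config seed.
#'
#' @param dir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @return Invisibly, the named list of file paths.
#' @export
as_simulate <- function(dir, config = simulation_config()) {
  config <- validate_simulation_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  paths <- .sim_files(dir)

  panel <- synthetic_panel()
  genome <- synthetic_reference(panel, seed = config$seed + 106)
  sigset <- synthetic_signature_set()
  meta_g <- generate_cohort(config, "genomic")
  meta_i <- generate_cohort(config, "immunology")
  meta <- rbind(meta_g, meta_i)
  dens <- generate_densities(meta, config)
  gv <- generate_variants(meta_g, panel, config, genome, sigset)
  gc_ <- generate_coverage(meta_g, panel, config)

  Biostrings::writeXStringSet(genome, paths$fasta, width = 80)
  write_panel_bed(panel, paths$panel_bed)
  tert <- panel$tert
  yaml::write_yaml(list(
    splice_flank_bp = panel$splice_flank_bp,
    tert_promoter = list(contig = as.character(GenomicRanges::seqnames(tert)),
                         start = GenomicRanges::start(tert),
                         end = GenomicRanges::end(tert))), paths$panel_yaml)
  write_vcf(gv$variants, paths$vcf, samples = meta_g$sample_id,
            contig_lengths = stats::setNames(Biostrings::width(genome),
                                             names(genome)))
  write_coverage_tsv(gc_$coverage, paths$coverage)
  write_density_tsv(dens, paths$densities)
  write_metadata_tsv(meta, paths$metadata)
  write_signature_tsv(sigset, paths$signatures)
  truth <- list(seed = config$seed,
                samples = gv$truth$samples,
                allelic = gv$truth$allelic,
                amplifications = gc_$amplifications)
  jsonlite::write_json(truth, paths$truth, dataframe = "rows",
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

.analysis_files <- function(dir) {
  list(filtered_variants = file.path(dir, "filtered_variants.tsv"),
       filter_counts = file.path(dir, "filter_counts.tsv"),
       tmb = file.path(dir, "tmb.tsv"),
       amplification_calls = file.path(dir, "amplification_calls.tsv"),
       allelic_calls = file.path(dir, "allelic_calls.tsv"),
       exposures = file.path(dir, "exposures.tsv"),
       density_summary = file.path(dir, "density_summary.tsv"),
       prevalence = file.path(dir, "prevalence.tsv"),
       integration = file.path(dir, "integration.tsv"))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline over a study directory
#'
#' Orchestrates the stages in order: variant filtering, TMB, amplification
#' calling with purity correction, allelic-state assessment, signature
#' refitting for TMB-high samples, cohort statistics, and the integration
#' table. Every stage's table is written to `outdir` before the next
#' consumes it. Samples below the purity floor are excluded from the
#' genomic stages.
#'
#' @param dir Study directory (as written by [as_simulate()], or any
#'   directory with the same file layout).
#' @param outdir Output directory (default `file.path(dir, "analysis")`).
#' @param thresholds A [run_config()].
#' @return Invisibly, a list of all result tables plus output paths.
#' @export
as_analyze <- function(dir, outdir = file.path(dir, "analysis"),
                       thresholds = run_config()) {
  inp <- .sim_files(dir)
  for (f in c("vcf", "coverage", "densities", "metadata", "panel_bed", "fasta")) {
    if (!file.exists(inp[[f]])) stop("missing input file: ", inp[[f]])
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- .analysis_files(outdir)

  pinfo <- if (file.exists(inp$panel_yaml)) yaml::read_yaml(inp$panel_yaml) else
    list(splice_flank_bp = thresholds$splice_flank_bp, tert_promoter = NULL)
  panel <- load_panel(inp$panel_bed,
                      splice_flank_bp = pinfo$splice_flank_bp,
                      tert_interval = pinfo$tert_promoter)
  genome <- Biostrings::readDNAStringSet(inp$fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  meta <- read_metadata_tsv(inp$metadata)
  dens <- read_density_tsv(inp$densities)
  variants <- read_vcf(inp$vcf)
  coverage <- read_coverage_tsv(inp$coverage)
  sigset <- if (file.exists(inp$signatures)) read_signature_tsv(inp$signatures)
    else synthetic_signature_set()

  orphan <- setdiff(unique(variants$sample_id), meta$sample_id)
  if (length(orphan))
    stop("sample(s) present in VCF but absent from metadata: ",
         paste(orphan, collapse = ", "))

  gmeta <- meta[(if ("arm" %in% names(meta)) meta$arm == "genomic" else
                   !is.na(meta$purity)), , drop = FALSE]
  low <- gmeta$sample_id[is.na(gmeta$purity) |
                           gmeta$purity < thresholds$min_purity]
  if (length(low))
    message("excluding ", length(low),
            " sample(s) below the purity floor (",
            thresholds$min_purity, "): ", paste(low, collapse = ", "))
  gmeta <- gmeta[!gmeta$sample_id %in% low, , drop = FALSE]
  variants <- variants[variants$sample_id %in% gmeta$sample_id, , drop = FALSE]

  # 1. filter cascade
  outcomes <- apply_filters(variants, panel,
                            pop_af_threshold = thresholds$pop_af_threshold,
                            vaf_threshold = thresholds$vaf_threshold)
  reportable <- reportable_set(outcomes)
  eligible <- tmb_eligible_set(outcomes)
  .write_tsv(reportable, out$filtered_variants)
  .write_tsv(filter_counts(outcomes, by_sample = TRUE), out$filter_counts)

  # 2. TMB
  tmb_results <- compute_tmb(eligible, panel, sample_ids = gmeta$sample_id,
                             cutoff = thresholds$tmb_high_cutoff)
  .write_tsv(tmb_results, out$tmb)

  # 3. amplification calling
  cov <- coverage[rownames(coverage) %in% gmeta$sample_id, , drop = FALSE]
  ratios <- relative_coverage(cov)
  purity <- stats::setNames(gmeta$purity, gmeta$sample_id)
  amp_calls <- call_amplifications(ratios,
                                   threshold = thresholds$amp_ratio_threshold,
                                   purity = purity)
  .write_tsv(amp_calls, out$amplification_calls)

  # 4. allelic state of class-4/5 tumor-suppressor hits
  allelic <- assess_cohort_allelic_state(reportable, gmeta,
                                         amp_calls = amp_calls)
  .write_tsv(allelic, out$allelic_calls)

  # 5. signature refitting for TMB-high samples
  sig_samples <- select_signature_samples(tmb_results)
  snv <- eligible[nchar(eligible$ref) == 1 & nchar(eligible$alt) == 1, ,
                  drop = FALSE]
  expo <- lapply(sig_samples, function(s) {
    cat96 <- build_catalog(snv[snv$sample_id == s, , drop = FALSE], genome,
                           sample_id = s)
    if (sum(cat96) == 0) return(NULL)
    fit_exposures(cat96, sigset,
                  min_mutations = thresholds$min_signature_mutations)
  })
  expo <- Filter(Negate(is.null), expo)
  expo_df <- if (length(expo)) do.call(rbind, lapply(expo, function(e)
    data.frame(sample_id = e$sample_id, t(e$exposures),
               cosine = e$cosine, n_mutations = e$n_mutations,
               status = e$status, check.names = FALSE)))
  else data.frame(sample_id = character(0))
  .write_tsv(expo_df, out$exposures)

  # 6. cohort statistics
  imeta <- if ("arm" %in% names(meta))
    meta[meta$arm == "immunology", , drop = FALSE] else meta
  dens_sum <- summarize_densities(dens[dens$sample_id %in% imeta$sample_id, ,
                                       drop = FALSE], imeta)
  .write_tsv(dens_sum, out$density_summary)

  gsets <- gene_sets()
  path_var <- reportable[reportable$pathogenicity_class %in% c("4", "5"), ,
                         drop = FALSE]
  amp_yes <- amp_calls[amp_calls$amplified, , drop = FALSE]
  features <- data.frame(sample_id = gmeta$sample_id)
  features$any_pathogenic <- features$sample_id %in% path_var$sample_id
  features$ddr_mutated <- features$sample_id %in%
    path_var$sample_id[path_var$gene %in% gsets$ddr_genes]
  features$any_amplification <- features$sample_id %in% amp_yes$sample_id
  features$tmb_high <- features$sample_id %in%
    tmb_results$sample_id[tmb_results$tmb_high]
  for (g in gsets$amplification_genes)
    features[[paste0("amp_", g)]] <- features$sample_id %in%
      amp_yes$sample_id[amp_yes$gene == g]
  prev <- feature_prevalence(features, gmeta)
  .write_tsv(prev$cluster, out$prevalence)

  # 7. integration table
  integration <- build_integration_table(tmb_results, amp_calls, reportable,
                                         dens, gmeta, gsets = gsets)
  .write_tsv(integration, out$integration)

  invisible(list(panel = panel, outcomes = outcomes, tmb = tmb_results,
                 amplification_calls = amp_calls, allelic = allelic,
                 exposures = expo, density_summary = dens_sum,
                 prevalence = prev, integration = integration,
                 excluded_low_purity = low, paths = out))
}

.fmt_tbl <- function(df) {
  txt <- utils::capture.output(print(df, row.names = FALSE, digits = 4))
  paste(txt, collapse = "\n")
}

#' Write a plain-text cohort report
#'
#' Summarizes an [as_analyze()] output directory: per-cluster and
#' per-subgroup TMB medians and ranges, genomic-feature prevalences with
#' Fisher p-values, immune-density comparisons, and per-rule filter
#' removal counts. Re-running on unchanged inputs reproduces the report
#' byte for byte.
#'
#' @param dir Study directory.
#' @param outdir Analysis directory (default `file.path(dir, "analysis")`).
#' @param path Report path (default `report.txt` inside `outdir`).
#' @return `path`, invisibly.
#' @export
as_report <- function(dir, outdir = file.path(dir, "analysis"),
                      path = file.path(outdir, "report.txt")) {
  out <- .analysis_files(outdir)
  for (f in c("tmb", "filter_counts", "prevalence", "density_summary")) {
    if (!file.exists(out[[f]])) stop("missing analysis output: ", out[[f]],
                                     " (run as_analyze first)")
  }
  tmb <- utils::read.delim(out$tmb)
  meta <- read_metadata_tsv(.sim_files(dir)$metadata)
  tsum <- summarize_tmb(tmb, meta)
  fc <- utils::read.delim(out$filter_counts)
  fc_tot <- stats::aggregate(removed ~ rule, fc, sum)
  prev <- utils::read.delim(out$prevalence)
  dens <- utils::read.delim(out$density_summary)

  lines <- c(
    "Angiosarcoma cohort report",
    "==========================",
    "",
    sprintf("Genomic samples analyzed: %d (TMB-high: %d)",
            nrow(tmb), sum(tmb$tmb_high)),
    "",
    "TMB by cluster (mut/Mb):", .fmt_tbl(tsum$cluster), "",
    "TMB by subgroup (mut/Mb):", .fmt_tbl(tsum$subgroup), "",
    "Variant filter removals (all samples):", .fmt_tbl(fc_tot), "",
    "Genomic feature prevalence (primary vs secondary):", .fmt_tbl(prev), "",
    "Immune-cell densities (cells/mm^2, primary vs secondary):",
    .fmt_tbl(dens), "")
  writeLines(lines, path)
  invisible(path)
}
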