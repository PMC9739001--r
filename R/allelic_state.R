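#' Classify a tumor-suppressor hit as mono- or biallelic
#'
#' For class-4/5 variants in a tumor suppressor gene, decides whether one
#' or both alleles are affected using a three-tier evidence hierarchy:
#'
#' 1. **second hit** — two or more distinct class-4/5 variants in the gene
#'    are taken as compound inactivation;
#' 2. **loh_vaf** — a one-sided binomial test rejects the heterozygous
#'    model (expected VAF `purity / 2`) upward while the
#'    loss-of-heterozygosity model (expected VAF `purity / (2 - purity)`,
#'    the mutant fraction after loss of the wild-type allele) is not
#'    rejected;
#' 3. **loh_snp** — with at least 3 nearby heterozygous SNPs, the median
#'    allele-fraction deviation from 0.5 exceeds half the LOH-expected
#'    shift `purity / (2 * (2 - purity))`.
#'
#' Otherwise the call is monoallelic. Calls are indeterminate when the
#' variant depth is below `min_depth`, purity is unknown, or the gene is
#' itself amplified (the diploid-background VAF model does not apply).
#'
#' @param variants data.frame of the class-4/5 variants of ONE gene in ONE
#'   sample, with columns `gene`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_depth` (and optionally `sample_id`).
#' @param purity Tumor cell fraction in (0, 1], or NA.
#' @param nearby_snp_afs Optional numeric vector of allele fractions of
#'   heterozygous SNPs near the gene (default none).
#' @param alpha Test level for the binomial comparisons (default 0.05).
#' @param amplified Is the gene amplified in this sample?
#' @param min_depth Minimum variant depth for a VAF-based call (default 50).
#' @return One-row data.frame: `sample_id`, `gene`, `state`
#'   (`monoallelic` / `biallelic` / `indeterminate`), `mechanism`
#'   (`second_hit` / `loh_vaf` / `loh_snp` / `none`), `vaf`,
#'   `expected_het_vaf`, `expected_loh_vaf`, `snp_deviation`.
#' @export
assess_allelic_state <- function(variants, purity, nearby_snp_afs = NULL,
                                 alpha = 0.05, amplified = FALSE,
                                 min_depth = 50) {
  if (!nrow(variants)) stop("no variants supplied for allelic-state assessment")
  gene <- variants$gene[1]
  sid <- if ("sample_id" %in% names(variants)) variants$sample_id[1] else NA_character_
  key <- paste(variants$pos, variants$ref, variants$alt)
  n_distinct <- length(unique(key))
  # use the best-covered variant as the VAF witness
  i <- which.max(variants$depth)
  depth <- variants$depth[i]; alt <- variants$alt_depth[i]
  vaf <- alt / depth
  e_het <- if (is.na(purity)) NA_real_ else purity / 2
  e_loh <- if (is.na(purity)) NA_real_ else purity / (2 - purity)
  snp_dev <- if (!is.null(nearby_snp_afs) && length(nearby_snp_afs) >= 3)
    stats::median(abs(nearby_snp_afs - 0.5)) else NA_real_

  res <- function(state, mechanism) data.frame(
    sample_id = sid, gene = gene, state = state, mechanism = mechanism,
    vaf = vaf, expected_het_vaf = e_het, expected_loh_vaf = e_loh,
    snp_deviation = snp_dev, row.names = NULL)

  if (n_distinct >= 2) return(res("biallelic", "second_hit"))
  if (amplified || is.na(purity) || depth < min_depth)
    return(res("indeterminate", "none"))

  p_het_up <- stats::binom.test(alt, depth, p = e_het,
                                alternative = "greater")$p.value
  p_loh <- stats::binom.test(alt, depth, p = e_loh,
                             alternative = "two.sided")$p.value
  if (p_het_up < alpha && p_loh >= alpha) return(res("biallelic", "loh_vaf"))

  if (!is.na(snp_dev) && snp_dev > purity / (2 * (2 - purity)) / 2)
    return(res("biallelic", "loh_snp"))

  res("monoallelic", "none")
}

#' Assess allelic state across a cohort
#'
#' Runs [assess_allelic_state()] for every (sample, gene) pair carrying a
#' class-4/5 variant in a tumor suppressor gene.
#'
#' @param variants Filtered (reportable) variants data.frame.
#' @param meta Sample metadata (supplies purity).
#' @param gsets A [gene_sets()] object; only `tsg_genes` are assessed.
#' @param amp_calls Optional amplification calls; amplified genes yield
#'   indeterminate allelic state.
#' @param ... Passed to [assess_allelic_state()].
#' @return data.frame of allelic calls (possibly zero rows).
#' @export
assess_cohort_allelic_state <- function(variants, meta, gsets = gene_sets(),
                                        amp_calls = NULL, ...) {
  sel <- variants$pathogenicity_class %in% c("4", "5") &
    variants$gene %in% gsets$tsg_genes
  v <- variants[sel, , drop = FALSE]
  if (!nrow(v)) {
    return(data.frame(sample_id = character(0), gene = character(0),
                      state = character(0), mechanism = character(0),
                      vaf = numeric(0), expected_het_vaf = numeric(0),
                      expected_loh_vaf = numeric(0), snp_deviation = numeric(0)))
  }
  purity <- stats::setNames(meta$purity, meta$sample_id)
  pieces <- lapply(split(v, list(v$sample_id, v$gene), drop = TRUE), function(d) {
    amp <- FALSE
    if (!is.null(amp_calls)) {
      hit <- amp_calls$sample_id == d$sample_id[1] & amp_calls$gene == d$gene[1]
      amp <- any(amp_calls$amplified[hit])
    }
    assess_allelic_state(d, purity = unname(purity[d$sample_id[1]]),
                         amplified = amp, ...)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$sample_id, out$gene), , drop = FALSE]
}
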