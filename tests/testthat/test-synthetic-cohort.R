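test_that("default cohorts have the study's arm sizes and purity floor", {
  cfg <- simulation_config(seed = 1)
  gi <- generate_cohort(cfg, "immunology")
  expect_equal(sum(gi$cluster == "primary"), 79)
  expect_equal(sum(gi$cluster == "secondary"), 178)
  expect_true(all(is.na(gi$purity)))
  gg <- generate_cohort(cfg, "genomic")
  expect_equal(as.integer(table(gg$cluster)[c("primary", "secondary")]),
               c(25L, 25L))
  expect_true(all(gg$purity >= 0.30))
  expect_equal(as.integer(table(gg$subgroup)[subgroup_levels()]),
               as.integer(cfg$n_genomic[subgroup_levels()]))
})

test_that("cohort generation is deterministic and rejects empty configs", {
  cfg <- simulation_config(seed = 77)
  expect_identical(generate_cohort(cfg, "genomic"),
                   generate_cohort(cfg, "genomic"))
  zero <- stats::setNames(rep(0L, 8), subgroup_levels())
  expect_error(generate_cohort(simulation_config(seed = 1, n_genomic = zero),
                               "genomic"), "zero samples")
})

test_that("config validation rejects impossible parameters", {
  expect_error(simulation_config(seed = 1, purity_range = c(0.1, 0.9)),
               "0.30")
  expect_error(simulation_config(seed = 1,
                                 ddr_mutation_probability = c(primary = 1.2,
                                                              secondary = 0.5)),
               "probabilities")
  bad_mix <- .5 * simulation_config(seed = 1)$signature_mix
  expect_error(simulation_config(seed = 1, signature_mix = bad_mix), "sum to 1")
  expect_error(simulation_config(seed = 1, nonsense_field = 3), "unknown")
})

test_that("density draws hit the configured medians and IQRs", {
  cfg <- simulation_config(seed = 42)
  big <- stats::setNames(c(0L, 0L, 0L, 0L, 0L, 0L, 2000L, 0L), subgroup_levels())
  meta <- generate_cohort(simulation_config(seed = 42, n_immune = big),
                          "immunology")
  dens <- generate_densities(meta, cfg)
  med <- stats::median(dens$CD3)
  expect_lt(abs(med - 817) / 817, 0.15)    # UV CD3 configured median 817
  iqr <- diff(stats::quantile(dens$CD3, c(0.25, 0.75), names = FALSE))
  expect_lt(abs(iqr - 862) / 862, 0.25)
  # NK cells: median 0, never above 30
  expect_equal(stats::median(dens$CD56), 0)
  expect_lte(max(dens$CD56), 30)
})

test_that("zero IQR collapses the density distribution onto the median", {
  cfg <- simulation_config(seed = 42)
  cfg$density$iqr[] <- 0
  meta <- generate_cohort(cfg, "genomic")
  dens <- generate_densities(meta, cfg)
  uv <- dens$CD3[meta$subgroup == "uv"]
  expect_true(all(uv == 817))
})

test_that("non-positive density medians are rejected", {
  cfg <- simulation_config(seed = 42)
  cfg$density$median["CD3", "uv"] <- 0
  meta <- generate_cohort(simulation_config(seed = 42), "genomic")
  expect_error(generate_densities(meta, cfg), "positive")
})

test_that("pure UV spectra produce mostly dipyrimidine C>T variants", {
  cfg <- simulation_config(seed = 9)
  mix <- cfg$signature_mix
  mix[] <- 0; mix[, "SBS7b"] <- 1
  one <- stats::setNames(c(0L, 0L, 0L, 0L, 0L, 0L, 3L, 0L), subgroup_levels())
  cfg2 <- simulation_config(seed = 9, signature_mix = mix, n_genomic = one,
                            tmb_rate = stats::setNames(rep(40, 8),
                                                       subgroup_levels()))
  panel <- synthetic_panel()
  genome <- synthetic_reference(panel, seed = 5)
  meta <- generate_cohort(cfg2, "genomic")
  gv <- generate_variants(meta, panel, cfg2, genome)
  som <- gv$variants[gv$variants$pathogenicity_class == "3" &
                       gv$variants$consequence != "promoter", ]
  ctx <- vapply(seq_len(nrow(som)), function(i) {
    as.character(Biostrings::extractAt(
      genome[[1]], IRanges::IRanges(som$pos[i] - 1, som$pos[i] + 1)))
  }, "")
  ch <- sbs_channel_of(som$ref, som$alt, ctx)
  is_ct <- grepl("C>T", ch)
  dipyr <- substr(ch, 1, 1) %in% c("C", "T")
  expect_gte(mean(is_ct & dipyr), 0.6)
})

test_that("nuisance variant counts are exact per sample", {
  d <- study_fixture()
  truth <- truth_fixture()
  vars <- read_vcf(file.path(d, "cohort.vcf"))
  cfg <- simulation_config(seed = 20221130)
  for (sid in truth$samples$sample_id[1:5]) {
    sv <- vars[vars$sample_id == sid, ]
    expect_equal(sum(sv$alt_depth / sv$depth < 0.05 &
                       sv$pathogenicity_class == "unknown" &
                       sv$consequence != "other"),
                 cfg$n_low_vaf_artifacts)
    expect_equal(sum(sv$pop_af > 0.001), cfg$n_common_germline_variants)
    expect_equal(sum(sv$consequence == "other"), cfg$n_off_target_variants)
  }
})

test_that("somatic VAFs track purity under the binomial depth model", {
  panel <- synthetic_panel()
  genome <- synthetic_reference(panel, seed = 5)
  one <- stats::setNames(c(0L, 0L, 0L, 3L, 0L, 0L, 0L, 0L), subgroup_levels())
  cfg <- simulation_config(seed = 3, n_genomic = one,
                           mean_depth = 1000,
                           n_common_germline_variants = 0,
                           n_low_vaf_artifacts = 0, n_off_target_variants = 0,
                           tmb_rate = stats::setNames(rep(30, 8),
                                                      subgroup_levels()),
                           ddr_mutation_probability = c(primary = 0,
                                                        secondary = 0),
                           driver_probability = c(primary = 0, secondary = 0))
  meta <- generate_cohort(cfg, "genomic")
  meta$purity <- 0.5
  gv <- generate_variants(meta, panel, cfg, genome)
  vafs <- gv$variants$alt_depth / gv$variants$depth
  expect_equal(mean(vafs), 0.25, tolerance = 0.03)
})

test_that("coverage encodes amplifications through the purity mixture", {
  expect_equal(expected_relative_coverage(2, 0.7), 1.0)
  expect_equal(expected_relative_coverage(8, 1.0), 4.0)
  expect_equal(expected_relative_coverage(8, 0.5), 2.5)
  cfg <- simulation_config(seed = 5)
  meta <- generate_cohort(cfg, "genomic")
  panel <- synthetic_panel()
  gc_ <- generate_coverage(meta, panel, cfg)
  expect_equal(dim(gc_$coverage), c(50L, 100L))
  expect_true(all(gc_$coverage > 0))
  # every truth event must clear the calling threshold in expectation
  expect_true(all(gc_$amplifications$expected_ratio >= 3))
})

test_that("DDR prevalence converges to the configured cluster rates", {
  big <- stats::setNames(rep(50L, 8), subgroup_levels())
  cfg <- simulation_config(seed = 11, n_genomic = big,
                           tmb_rate = stats::setNames(rep(0.5, 8),
                                                      subgroup_levels()))
  panel <- synthetic_panel()
  genome <- synthetic_reference(panel, seed = 5)
  meta <- generate_cohort(cfg, "genomic")
  gv <- generate_variants(meta, panel, cfg, genome)
  tr <- gv$truth$samples
  # observed fractions are statistically consistent with the configured rates
  for (cl in c("primary", "secondary")) {
    k <- sum(tr$ddr_mutated[tr$cluster == cl])
    n <- sum(tr$cluster == cl)
    target <- c(primary = 0.24, secondary = 0.60)[[cl]]
    expect_gt(stats::binom.test(k, n, p = target)$p.value, 1e-3)
  }
})

test_that("generated files round-trip through their readers unchanged", {
  d <- study_fixture()
  vars <- read_vcf(file.path(d, "cohort.vcf"))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vars, tmp, samples = sort(unique(vars$sample_id)))
  vars2 <- read_vcf(tmp)
  ord <- function(v) {
    v <- v[order(v$sample_id, v$contig, v$pos, v$alt), ]
    rownames(v) <- NULL
    v
  }
  expect_equal(ord(vars2), ord(vars))

  cov <- read_coverage_tsv(file.path(d, "coverage.tsv"))
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_tsv(cov, tmp2)
  expect_equal(read_coverage_tsv(tmp2), cov)

  dens <- read_density_tsv(file.path(d, "densities.tsv"))
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  write_density_tsv(dens, tmp3)
  expect_equal(read_density_tsv(tmp3), dens)

  meta <- read_metadata_tsv(file.path(d, "metadata.tsv"))
  expect_equal(nrow(meta), 50 + 257)
})
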