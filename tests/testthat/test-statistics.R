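test_that("Fisher exact reproduces published contingency-table p-values", {
  expect_equal(round(fisher_exact_two_sided(
    matrix(c(6, 19, 15, 10), 2, 2, byrow = TRUE)), 3), 0.021)
  expect_equal(round(fisher_exact_two_sided(
    matrix(c(20, 5, 22, 3), 2, 2, byrow = TRUE)), 3), 0.702)
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2, 2)), 1.0)
  expect_equal(round(fisher_exact_two_sided(
    matrix(c(0, 25, 5, 20), 2, 2, byrow = TRUE)), 3), 0.050)
})

test_that("degenerate and invalid tables are handled", {
  expect_message(p <- fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2, 2)),
                 "degenerate")
  expect_equal(p, 1)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2, 2)),
               "non-negative")
  expect_error(fisher_exact_two_sided(matrix(1, 3, 3)), "2x2")
})

test_that("Fisher matches the enumeration oracle over all small tables", {
  # every 2x2 table with N <= 40, via margins x observed cell
  worst <- 0
  for (n in 1:40) {
    for (r1 in 1:(n - 1)) {
      for (c1 in 1:(n - 1)) {
        lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
        for (a in lo:hi) {
          tab <- matrix(c(a, r1 - a, c1 - a, n - r1 - c1 + a), 2, 2,
                        byrow = TRUE)
          worst <- max(worst, abs(fisher_exact_two_sided(tab) -
                                    fisher_oracle(tab)))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("Fisher agrees with the independent base implementation", {
  set.seed(5)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8) + 1, 2, 2)
    expect_equal(fisher_exact_two_sided(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-6)
  }
})

test_that("Mann-Whitney exact mode matches the rank-split oracle", {
  set.seed(31)
  for (na in 1:6) {
    for (nb in 1:6) {
      a <- stats::rnorm(na); b <- stats::rnorm(nb)
      got <- mann_whitney_u(a, b)
      expect_equal(got$method, "exact")
      expect_equal(got$p_value, mw_oracle(a, b), tolerance = 1e-12,
                   info = sprintf("na=%d nb=%d", na, nb))
    }
  }
})

test_that("Mann-Whitney endpoints behave as expected", {
  sep <- mann_whitney_u(1:3, 4:6)
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 0.1)   # 2/20 rank splits as extreme
  rev <- mann_whitney_u(4:6, 1:3)
  expect_equal(rev$U, 9)           # n_a * n_b
  expect_equal(rev$p_value, 0.1)
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)          # n_a * n_b / 2
  expect_equal(same$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney approximation matches the reference implementation", {
  set.seed(99)
  a <- stats::rlnorm(60, 5, 1); b <- stats::rlnorm(80, 5.4, 1)
  got <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$method, "normal_approx")
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$U, unname(ref$statistic))
  # tie-heavy data exercises the tie correction
  a <- sample(1:5, 40, replace = TRUE); b <- sample(2:6, 50, replace = TRUE)
  got <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("density summaries report type-7 medians and IQRs per group", {
  dens <- data.frame(sample_id = sprintf("S%d", 1:8),
                     CD3 = c(10, 20, 30, 40, 10, 20, 30, 40))
  meta <- data.frame(sample_id = sprintf("S%d", 1:8),
                     cluster = rep(c("primary", "secondary"), each = 4),
                     subgroup = rep(c("visceral", "uv"), each = 4),
                     purity = NA)
  s <- summarize_densities(dens, meta, markers = "CD3")
  expect_equal(s$median_a, 25)
  expect_equal(s$iqr_a, 15)        # type-7: Q1 17.5, Q3 32.5
  expect_gt(s$p_value, 0.9)        # identical groups
})

test_that("missing marker values drop the sample with a warning", {
  dens <- data.frame(sample_id = sprintf("S%d", 1:6),
                     CD3 = c(1, 2, NA, 10, 20, 30))
  meta <- data.frame(sample_id = sprintf("S%d", 1:6),
                     cluster = rep(c("primary", "secondary"), each = 3),
                     subgroup = rep(c("visceral", "uv"), each = 3),
                     purity = NA)
  expect_warning(s <- summarize_densities(dens, meta, markers = "CD3"),
                 "dropped")
  expect_equal(s$n_a, 2)
})

test_that("feature prevalence reproduces fixture counts and percents", {
  ids <- sprintf("S%02d", 1:50)
  meta <- data.frame(sample_id = ids,
                     cluster = rep(c("primary", "secondary"), each = 25),
                     subgroup = rep(c("visceral", "rt"), each = 25),
                     purity = 0.5)
  feats <- data.frame(sample_id = ids,
                      ddr = c(rep(TRUE, 6), rep(FALSE, 19),
                              rep(TRUE, 15), rep(FALSE, 10)),
                      myc = c(rep(TRUE, 4), rep(FALSE, 21),
                              rep(TRUE, 17), rep(FALSE, 8)),
                      never = FALSE)
  prev <- feature_prevalence(feats, meta)
  ddr <- prev$cluster[prev$cluster$feature == "ddr", ]
  expect_equal(c(ddr$pct_primary, ddr$pct_secondary), c(24, 60))
  expect_equal(round(ddr$p_value, 3), 0.021)
  myc <- prev$cluster[prev$cluster$feature == "myc", ]
  expect_equal(c(myc$pct_primary, myc$pct_secondary), c(16, 68))
  nv <- prev$cluster[prev$cluster$feature == "never", ]
  expect_equal(c(nv$pct_primary, nv$pct_secondary, nv$p_value), c(0, 0, 1))
  expect_equal(prev$tables$ddr,
               matrix(c(6L, 19L, 15L, 10L), 2, 2, byrow = TRUE,
                      dimnames = list(c("primary", "secondary"),
                                      c("yes", "no"))))
})

test_that("integration table filters singleton genes and keeps schema", {
  ids <- sprintf("S%d", 1:4)
  meta <- data.frame(sample_id = ids,
                     cluster = c("primary", "primary", "secondary", "secondary"),
                     subgroup = c("visceral", "visceral", "rt", "rt"),
                     purity = 0.5)
  tmb <- data.frame(sample_id = ids, n_eligible = 1, effective_size_mb = 1,
                    tmb = 1, tmb_high = FALSE)
  # TP53 mutated in two samples; SINGLETON in one; MYC amplified in two
  vars <- rbind(make_variant(gene = "TP53", pathogenicity_class = "5",
                             sample_id = "S1"),
                make_variant(gene = "TP53", pathogenicity_class = "4",
                             sample_id = "S3"),
                make_variant(gene = "SINGLETON", pathogenicity_class = "5",
                             sample_id = "S2"))
  amps <- data.frame(sample_id = c("S3", "S4"), gene = "MYC",
                     relative_coverage = 4, amplified = TRUE,
                     estimated_copies = 8)
  dens <- data.frame(sample_id = ids, CD3 = 100, CD8 = 50, FoxP3 = 10,
                     CD4 = 60, CD20 = 20)
  tab <- build_integration_table(tmb, amps, vars, dens, meta)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("mut_TP53", "amp_TP53", "mut_MYC", "amp_MYC") %in% names(tab)))
  expect_false("mut_SINGLETON" %in% names(tab))  # altered in only one sample
  # fixed columns + 2 selected genes x 2 + 5 densities
  expect_equal(ncol(tab), 7 + 2 * 2 + 5)
  expect_equal(tab$mut_TP53[tab$sample_id == "S1"], "5")
  expect_true(tab$amp_MYC[tab$sample_id == "S4"])
  # sample without alterations keeps its densities
  s2 <- tab[tab$sample_id == "S4", ]
  expect_equal(s2$CD3, 100)
  full <- build_integration_table(tmb, amps, vars, dens, meta, min_samples = 1)
  expect_true("mut_SINGLETON" %in% names(full))
})

test_that("prevalence is re-derivable from the integration table", {
  res <- analysis_fixture()
  tab <- res$integration
  prev <- res$prevalence$cluster
  myc <- prev[prev$feature == "amp_MYC", ]
  if ("amp_MYC" %in% names(tab)) {
    expect_equal(sum(tab$amp_MYC[tab$cluster == "secondary"]),
                 myc$count_secondary)
    expect_equal(sum(tab$amp_MYC[tab$cluster == "primary"]),
                 myc$count_primary)
  }
  ddr <- prev[prev$feature == "ddr_mutated", ]
  expect_equal(sum(tab$ddr_mutated[tab$cluster == "secondary"]),
               ddr$count_secondary)
})
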