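#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration with the point-probability
#' ("minimum-likelihood") two-sided rule: the p-value is the sum of the
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table. Probability
#' comparisons use a small relative tolerance so that tables tied in
#' probability up to floating-point noise are included.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows = groups, columns = feature present/absent).
#' @param rel_tol Relative tolerance for probability ties (default 1e-12).
#' @return The two-sided p-value. Degenerate tables (a zero margin) give
#'   p = 1 with a message.
#' @export
fisher_exact_two_sided <- function(tab, rel_tol = 1e-12) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8))
    stop("table entries must be non-negative integers")
  tab <- round(tab)
  n <- sum(tab)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
  if (n == 0 || r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    message("degenerate 2x2 table (zero margin): p = 1")
    return(1)
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == tab[1, 1]]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

#' Mann-Whitney U test
#'
#' U is computed from midranks for the first group. The two-sided p-value
#' uses the exact U distribution when `n_a * n_b <= 400` and there are no
#' ties, and otherwise a normal approximation with tie correction and
#' continuity correction (the asymptotic convention of standard
#' statistical software).
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) mode;
#'   default `NULL` picks automatically.
#' @return List with `U` (for group `a`), `p_value`, and `method`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  x <- c(a, b)
  r <- rank(x)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(x) > 0
  if (is.null(exact)) exact <- (na * nb <= 400) && !ties
  if (exact && ties) exact <- FALSE
  if (exact) {
    p <- 2 * min(stats::pwilcox(u, na, nb),
                 1 - stats::pwilcox(u - 1, na, nb))
    p <- min(1, p)
    method <- "exact"
  } else {
    n <- na + nb
    tfreq <- table(x)
    s2 <- na * nb / 12 * ((n + 1) - sum(tfreq^3 - tfreq) / (n * (n - 1)))
    d <- u - na * nb / 2
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- (d - sign(d) * 0.5) / sqrt(s2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  list(U = u, p_value = p, method = method)
}

.iqr7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Compare immune-cell densities between two groups
#'
#' Per marker: median and interquartile range (type-7 quantiles) per
#' group, plus a two-sided Mann-Whitney p-value. Raw p-values are
#' reported; no multiplicity adjustment is applied.
#'
#' @param densities data.frame with `sample_id` and one column per marker
#'   (cells/mm^2).
#' @param meta Sample metadata (see [validate_sample_meta()]).
#' @param group_col Metadata column defining the two groups
#'   (default `"cluster"`).
#' @param markers Markers to compare.
#' @return data.frame, one row per marker: group ns, medians, IQRs, p.
#' @export
summarize_densities <- function(densities, meta,
                                group_col = "cluster",
                                markers = c("CD3", "CD8", "FoxP3", "CD4", "CD20")) {
  m <- merge(densities, meta[, c("sample_id", group_col)], by = "sample_id")
  groups <- sort(unique(m[[group_col]]))
  if (length(groups) != 2) stop("density comparison requires exactly two groups")
  rows <- lapply(markers, function(mk) {
    if (!mk %in% names(m)) stop("marker column missing: ", mk)
    v <- m[[mk]]
    keep <- !is.na(v)
    if (any(!keep))
      warning(sum(!keep), " sample(s) dropped for marker ", mk, " (missing value)")
    va <- v[keep & m[[group_col]] == groups[1]]
    vb <- v[keep & m[[group_col]] == groups[2]]
    mw <- mann_whitney_u(va, vb)
    data.frame(marker = mk,
               group_a = groups[1], n_a = length(va),
               median_a = stats::median(va), iqr_a = .iqr7(va),
               group_b = groups[2], n_b = length(vb),
               median_b = stats::median(vb), iqr_b = .iqr7(vb),
               U = mw$U, p_value = mw$p_value)
  })
  do.call(rbind, rows)
}

#' Prevalence of binary genomic features by cluster and subgroup
#'
#' For each boolean feature column: count/percent per cluster and per
#' subgroup, the cluster-level 2x2 contingency table, and its two-sided
#' Fisher exact p-value.
#'
#' @param features data.frame with `sample_id` plus logical feature
#'   columns (e.g. `ddr_mutated`, `any_pathogenic`, `amp_MYC`).
#' @param meta Sample metadata.
#' @return List with `cluster` (data.frame incl. `p_value`), `subgroup`
#'   (counts/percents per subgroup), and `tables` (named list of 2x2
#'   matrices).
#' @export
feature_prevalence <- function(features, meta) {
  m <- merge(features, meta[, c("sample_id", "cluster", "subgroup")],
             by = "sample_id")
  fcols <- setdiff(names(features), "sample_id")
  tables <- list()
  crow <- list(); srow <- list()
  for (f in fcols) {
    v <- as.logical(m[[f]])
    tab <- matrix(0L, 2, 2,
                  dimnames = list(c("primary", "secondary"), c("yes", "no")))
    for (cl in c("primary", "secondary")) {
      sel <- m$cluster == cl
      tab[cl, ] <- c(sum(v[sel]), sum(!v[sel]))
    }
    tables[[f]] <- tab
    p <- suppressMessages(fisher_exact_two_sided(tab))
    crow[[f]] <- data.frame(
      feature = f,
      n_primary = sum(tab["primary", ]), count_primary = tab["primary", "yes"],
      pct_primary = 100 * tab["primary", "yes"] / max(1, sum(tab["primary", ])),
      n_secondary = sum(tab["secondary", ]), count_secondary = tab["secondary", "yes"],
      pct_secondary = 100 * tab["secondary", "yes"] / max(1, sum(tab["secondary", ])),
      p_value = p)
    sg <- lapply(intersect(subgroup_levels(), unique(m$subgroup)), function(s) {
      sel <- m$subgroup == s
      data.frame(feature = f, subgroup = s, n = sum(sel), count = sum(v[sel]),
                 pct = 100 * sum(v[sel]) / max(1, sum(sel)))
    })
    srow[[f]] <- do.call(rbind, sg)
  }
  list(cluster = do.call(rbind, crow),
       subgroup = do.call(rbind, srow),
       tables = tables)
}

#' Per-sample integration table (genomic + immunological landscape)
#'
#' One row per sample combining subgroup, TMB, DDR status, per-gene
#' mutation class and amplification flags, and lymphocyte densities. By
#' default only genes altered (class 4/5 mutation or amplification) in at
#' least `min_samples` samples get columns, mirroring a recurrence-filtered
#' oncoprint; set `min_samples = 1` for the full table.
#'
#' @param tmb_results data.frame from [compute_tmb()].
#' @param amp_calls data.frame from [call_amplifications()].
#' @param variants Filtered (reportable) variants data.frame.
#' @param densities Density table (may omit samples).
#' @param meta Sample metadata (defines the rows).
#' @param gsets A [gene_sets()] object (defines the DDR flag).
#' @param min_samples Recurrence threshold for gene columns (default 2).
#' @return data.frame with one row per sample in `meta`.
#' @export
build_integration_table <- function(tmb_results, amp_calls, variants,
                                    densities, meta,
                                    gsets = gene_sets(), min_samples = 2) {
  meta <- validate_sample_meta(meta)
  out <- meta[, c("sample_id", "cluster", "subgroup", "purity")]
  out <- merge(out, tmb_results[, c("sample_id", "tmb", "tmb_high")],
               by = "sample_id", all.x = TRUE)

  path_var <- variants[!is.na(variants$pathogenicity_class) &
                         variants$pathogenicity_class %in% c("4", "5"), ,
                       drop = FALSE]
  amp <- amp_calls[amp_calls$amplified, , drop = FALSE]

  mut_n <- if (nrow(path_var))
    tapply(path_var$sample_id, path_var$gene, function(s) length(unique(s)))
  else integer(0)
  amp_n <- if (nrow(amp))
    tapply(amp$sample_id, amp$gene, function(s) length(unique(s)))
  else integer(0)
  alt_n <- tapply(
    c(as.integer(mut_n), as.integer(amp_n)),
    c(names(mut_n), names(amp_n)), sum)
  sel_genes <- sort(names(alt_n)[alt_n >= min_samples])

  ddr <- vapply(out$sample_id, function(s)
    any(path_var$sample_id == s & path_var$gene %in% gsets$ddr_genes), logical(1))
  out$ddr_mutated <- unname(ddr)

  for (g in sel_genes) {
    cls <- vapply(out$sample_id, function(s) {
      k <- path_var$pathogenicity_class[path_var$sample_id == s & path_var$gene == g]
      if (length(k)) as.character(max(as.integer(k))) else ""
    }, "")
    out[[paste0("mut_", g)]] <- unname(cls)
    out[[paste0("amp_", g)]] <- out$sample_id %in%
      amp$sample_id[amp$gene == g]
  }
  dens_cols <- intersect(c("CD3", "CD8", "FoxP3", "CD4", "CD20"), names(densities))
  out <- merge(out, densities[, c("sample_id", dens_cols)],
               by = "sample_id", all.x = TRUE)
  out[order(out$cluster, out$subgroup, out$sample_id), , drop = FALSE]
}
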