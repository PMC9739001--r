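#' Apply the four-rule somatic filter cascade
#'
#' Filters annotated small variants against the panel territory and
#' quality rules, evaluating every rule for every variant (no
#' short-circuiting) so per-rule removal counts are complete:
#'
#' * **R1 territory** — fails when the position lies outside exons, splice
#'   flanks and the TERT promoter.
#' * **R2 synonymous** — fails for synonymous variants not located in a
#'   splice-site region.
#' * **R3 population** — fails when the population allele frequency is
#'   strictly above 0.1% (missing frequency counts as 0: a variant absent
#'   from the population database is treated as novel).
#' * **R4 VAF** — fails when the variant allele frequency is strictly
#'   below 5%; boundary values survive both R3 and R4.
#'
#' Records with zero depth are flagged malformed and rejected outright
#' (not attributed to R4).
#'
#' @param variants data.frame of variant records with columns `contig`,
#'   `pos`, `ref`, `alt`, `gene`, `consequence`, `pop_af`, `depth`,
#'   `alt_depth`, `pathogenicity_class`, `sample_id`.
#' @param panel A `panel_definition`.
#' @param pop_af_threshold Population-frequency cutoff (default 0.001).
#' @param vaf_threshold VAF cutoff (default 0.05).
#' @return The input data.frame augmented with `category`, `vaf`,
#'   `fail_R1_territory` .. `fail_R4_vaf`, `malformed`, and `kept`.
#' @export
apply_filters <- function(variants, panel,
                          pop_af_threshold = 0.001, vaf_threshold = 0.05) {
  stopifnot(inherits(panel, "panel_definition"))
  v <- variants
  if (!nrow(v)) {
    empty <- v
    for (col in c("category")) empty[[col]] <- character(0)
    for (col in c("vaf")) empty[[col]] <- numeric(0)
    for (col in c("fail_R1_territory", "fail_R2_synonymous",
                  "fail_R3_population", "fail_R4_vaf", "malformed", "kept"))
      empty[[col]] <- logical(0)
    return(empty)
  }
  pop_af <- v$pop_af
  pop_af[is.na(pop_af)] <- 0
  malformed <- is.na(v$depth) | v$depth <= 0 | is.na(v$alt_depth) |
    v$alt_depth < 0 | v$alt_depth > pmax(v$depth, 0, na.rm = TRUE)
  vaf <- ifelse(malformed, NA_real_, v$alt_depth / v$depth)
  category <- in_territory(panel, v$contig, v$pos)

  v$category <- category
  v$vaf <- vaf
  v$fail_R1_territory <- category == "outside"
  v$fail_R2_synonymous <- v$consequence == "synonymous" & category != "splice"
  v$fail_R3_population <- pop_af > pop_af_threshold
  v$fail_R4_vaf <- !malformed & vaf < vaf_threshold
  v$malformed <- malformed
  v$kept <- !malformed & !v$fail_R1_territory & !v$fail_R2_synonymous &
    !v$fail_R3_population & !v$fail_R4_vaf
  v
}

#' Reportable variants (all rules passed)
#'
#' @param outcomes Output of [apply_filters()].
#' @return Order-preserving subset with `kept == TRUE`.
#' @export
reportable_set <- function(outcomes) {
  outcomes[outcomes$kept, , drop = FALSE]
}

#' TMB-eligible variants (synonymous re-admitted)
#'
#' Total TMB counts both synonymous and non-synonymous variants, so the
#' synonymous rule (R2) is waived while territory, population-frequency
#' and VAF rules still apply. Derived from the same filter outcomes as the
#' reportable set, guaranteeing the two are consistent.
#'
#' @param outcomes Output of [apply_filters()].
#' @return Subset of variants failing no rule except possibly R2.
#' @export
tmb_eligible_set <- function(outcomes) {
  keep <- !outcomes$malformed & !outcomes$fail_R1_territory &
    !outcomes$fail_R3_population & !outcomes$fail_R4_vaf
  outcomes[keep, , drop = FALSE]
}

#' Per-rule removal counts
#'
#' @param outcomes Output of [apply_filters()].
#' @param by_sample Also break counts down per sample.
#' @return data.frame of rule-level removal counts.
#' @export
filter_counts <- function(outcomes, by_sample = FALSE) {
  rules <- c("fail_R1_territory", "fail_R2_synonymous",
             "fail_R3_population", "fail_R4_vaf", "malformed")
  total <- data.frame(
    rule = c(sub("^fail_", "", rules[1:4]), "malformed"),
    removed = vapply(rules, function(r) sum(outcomes[[r]]), integer(1)),
    row.names = NULL)
  if (!by_sample) return(total)
  per <- do.call(rbind, lapply(split(outcomes, outcomes$sample_id), function(d) {
    data.frame(sample_id = d$sample_id[1],
               rule = c(sub("^fail_", "", rules[1:4]), "malformed"),
               removed = vapply(rules, function(r) sum(d[[r]]), integer(1)),
               row.names = NULL)
  }))
  rownames(per) <- NULL
  per
}
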