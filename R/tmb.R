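#' Compute total tumor mutational burden per sample
#'
#' Total TMB = TMB-eligible variants (synonymous and non-synonymous) per
#' megabase of effective panel territory. Samples with no eligible
#' variants get TMB 0, so `sample_ids` should list every analyzed sample.
#' TMB-high uses the inclusive cutoff: a sample exactly at `cutoff`
#' counts as high.
#'
#' @param eligible Variants from [tmb_eligible_set()].
#' @param panel A `panel_definition` (supplies `effective_size_mb`).
#' @param sample_ids Samples to report (default: those present in
#'   `eligible`).
#' @param cutoff TMB-high threshold in mut/Mb (default 10).
#' @return data.frame: `sample_id`, `n_eligible`, `effective_size_mb`,
#'   `tmb`, `tmb_high`.
#' @export
compute_tmb <- function(eligible, panel, sample_ids = NULL, cutoff = 10) {
  stopifnot(inherits(panel, "panel_definition"))
  mb <- panel$effective_size_mb
  if (!is.finite(mb) || mb <= 0) stop("panel effective size must be positive")
  if (is.null(sample_ids)) sample_ids <- sort(unique(eligible$sample_id))
  n <- vapply(sample_ids, function(s) sum(eligible$sample_id == s), integer(1))
  tmb <- n / mb
  data.frame(sample_id = sample_ids, n_eligible = unname(n),
             effective_size_mb = mb, tmb = unname(tmb),
             tmb_high = unname(tmb >= cutoff), row.names = NULL)
}

#' Summarize TMB by cluster and subgroup
#'
#' Median (standard order statistic), range, and TMB-high counts per
#' group. Empty groups are omitted with a warning.
#'
#' @param tmb_results data.frame from [compute_tmb()].
#' @param meta Sample metadata.
#' @return List of two data.frames, `cluster` and `subgroup`.
#' @export
summarize_tmb <- function(tmb_results, meta) {
  m <- merge(tmb_results, meta[, c("sample_id", "cluster", "subgroup")],
             by = "sample_id")
  summar <- function(groups, levels) {
    rows <- lapply(levels, function(g) {
      v <- m$tmb[groups == g]
      if (!length(v)) {
        warning("empty group omitted from TMB summary: ", g)
        return(NULL)
      }
      data.frame(group = g, n = length(v), median_tmb = stats::median(v),
                 min_tmb = min(v), max_tmb = max(v),
                 n_tmb_high = sum(m$tmb_high[groups == g]))
    })
    do.call(rbind, rows)
  }
  list(cluster = summar(m$cluster, c("primary", "secondary")),
       subgroup = summar(m$subgroup, intersect(subgroup_levels(),
                                               unique(m$subgroup))))
}
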