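#' Median-normalized relative coverage
#'
#' Per sample, gene coverages are divided by their baseline capture
#' weights and then by the per-sample median of the weighted coverages,
#' yielding a scale-free ratio with an expected value of 1 for a diploid
#' gene. A stable median requires at least 10 genes.
#'
#' @param coverage Numeric matrix, samples x genes (rownames = sample
#'   ids, colnames = genes), of mean per-gene coverage.
#' @param weights Optional named per-gene baseline weights (default 1,
#'   standing in for a panel of normals).
#' @return Matrix of relative coverages, same shape as `coverage`.
#' @export
relative_coverage <- function(coverage, weights = NULL) {
  coverage <- as.matrix(coverage)
  if (ncol(coverage) < 10)
    stop("at least 10 genes are required for median normalization")
  if (any(coverage < 0)) stop("coverage must be non-negative")
  if (is.null(weights)) {
    weights <- rep(1, ncol(coverage))
  } else {
    weights <- weights[colnames(coverage)]
    if (anyNA(weights)) stop("missing baseline weight for some genes")
  }
  adj <- sweep(coverage, 2, as.numeric(weights), "/")
  med <- apply(adj, 1, stats::median)
  if (any(med <= 0)) stop("all-zero (or non-positive median) coverage for some sample")
  sweep(adj, 1, med, "/")
}

#' Call gene amplifications from relative coverage
#'
#' A relative coverage at or above `threshold` (default 3, inclusive) is
#' called an amplification. When `purity` is supplied, the copy number of
#' amplified genes is estimated via [estimate_copies()].
#'
#' @param ratios Matrix from [relative_coverage()] (samples x genes), or a
#'   named vector for a single sample.
#' @param threshold Amplification cutoff on the ratio (default 3).
#' @param purity Optional named per-sample purity vector for copy-number
#'   estimation.
#' @return data.frame: `sample_id`, `gene`, `relative_coverage`,
#'   `amplified`, `estimated_copies` (NA unless amplified and purity
#'   known).
#' @export
call_amplifications <- function(ratios, threshold = 3, purity = NULL) {
  if (is.null(dim(ratios))) ratios <- matrix(ratios, nrow = 1,
    dimnames = list("sample", names(ratios)))
  if (any(!is.finite(ratios))) stop("ratios must be finite")
  df <- data.frame(
    sample_id = rep(rownames(ratios), times = ncol(ratios)),
    gene = rep(colnames(ratios), each = nrow(ratios)),
    relative_coverage = as.vector(ratios))
  df$amplified <- df$relative_coverage >= threshold
  df$estimated_copies <- NA_real_
  if (!is.null(purity)) {
    idx <- which(df$amplified & !is.na(purity[df$sample_id]))
    if (length(idx))
      df$estimated_copies[idx] <- estimate_copies(
        df$relative_coverage[idx], as.numeric(purity[df$sample_id[idx]]))
  }
  df[order(df$sample_id, df$gene), , drop = FALSE]
}

#' Expected relative coverage of an amplified gene
#'
#' Two-component mixture of diploid normal cells and tumor cells carrying
#' `copies` copies: `ratio = (1 - purity) + purity * copies / 2`.
#'
#' @param copies Tumor copy number.
#' @param purity Tumor cell fraction in (0, 1].
#' @return Expected relative coverage.
#' @export
expected_relative_coverage <- function(copies, purity) {
  stopifnot(all(purity > 0), all(purity <= 1), all(copies >= 0))
  (1 - purity) + purity * copies / 2
}

#' Purity-corrected copy-number estimate
#'
#' Inverts the diploid-background mixture model:
#' `copies = (2 * ratio - 2 * (1 - purity)) / purity`, floored at 0.
#'
#' @param ratio Relative coverage.
#' @param purity Tumor cell fraction in (0, 1].
#' @return Estimated copy number in tumor cells.
#' @export
estimate_copies <- function(ratio, purity) {
  if (any(purity <= 0) || any(purity > 1)) stop("purity must lie in (0, 1]")
  pmax(0, (2 * ratio - 2 * (1 - purity)) / purity)
}
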