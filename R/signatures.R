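#' The 96 single-base-substitution channels
#'
#' Standard COSMIC ordering: substitution class (C>A, C>G, C>T, T>A, T>C,
#' T>G) varying slowest, then the 5' base, then the 3' base, each in
#' A, C, G, T order. Labels use the `A[C>A]A` convention. All substitutions
#' are expressed on the pyrimidine strand.
#'
#' @return Character vector of 96 channel labels.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(f) paste0(f, "[", s, "]", bases)))
  }))
}

.complement <- function(x) chartr("ACGT", "TGCA", x)

.revcomp <- function(x) {
  vapply(strsplit(.complement(x), ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Map single SNVs to SBS channel labels
#'
#' Purine-reference substitutions are reverse-complemented onto the
#' pyrimidine strand before labeling, so e.g. a G>A change in a `T_G_T`
#' context maps to `A[C>T]A`.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Three-base reference context centred on the variant.
#' @return Character vector of channel labels (NA where the context is
#'   unusable, e.g. contains N).
#' @export
sbs_channel_of <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  out <- rep(NA_character_, n)
  ok <- !is.na(ref) & !is.na(alt) & !is.na(context) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    nchar(context) == 3 & !grepl("[^ACGT]", context) &
    substr(context, 2, 2) == ref & ref != alt
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; cx <- context[ok]
  pur <- r %in% c("A", "G")
  cx[pur] <- .revcomp(cx[pur])
  r[pur] <- .complement(r[pur])
  a[pur] <- .complement(a[pur])
  out[ok] <- paste0(substr(cx, 1, 1), "[", r, ">", a, "]", substr(cx, 3, 3))
  out
}

#' Build a 96-channel SBS catalog for one sample
#'
#' @param snvs data.frame of single-nucleotide variants with columns
#'   `contig`, `pos`, `ref`, `alt` (1-based positions, single bases).
#' @param genome A [Biostrings::DNAStringSet] holding the reference
#'   contigs the positions refer to.
#' @param sample_id Optional id carried on the result.
#' @return An `sbs_catalog`: named integer vector of 96 counts with
#'   attributes `sample_id` and `n_skipped` (SNVs without a usable
#'   context).
#' @export
build_catalog <- function(snvs, genome, sample_id = NA_character_) {
  channels <- sbs_channels()
  counts <- stats::setNames(integer(96), channels)
  skipped <- 0L
  if (nrow(snvs)) {
    ctx <- rep(NA_character_, nrow(snvs))
    for (ctg in unique(snvs$contig)) {
      idx <- which(snvs$contig == ctg)
      if (!ctg %in% names(genome)) next
      seqlen <- Biostrings::width(genome[ctg])
      p <- snvs$pos[idx]
      inb <- p >= 2 & p <= seqlen - 1
      if (any(inb)) {
        ctx[idx[inb]] <- as.character(Biostrings::extractAt(
          genome[[ctg]], IRanges::IRanges(p[inb] - 1, p[inb] + 1)))
      }
    }
    ch <- sbs_channel_of(snvs$ref, snvs$alt, ctx)
    skipped <- sum(is.na(ch))
    if (skipped) warning(skipped, " SNV(s) skipped: no usable trinucleotide context")
    tab <- table(factor(ch[!is.na(ch)], levels = channels))
    counts[] <- as.integer(tab)
  }
  structure(counts, sample_id = sample_id, n_skipped = skipped,
            class = c("sbs_catalog", "integer"))
}

#' Bundled synthetic SBS signature set
#'
#' Five column-stochastic 96-channel spectra built in code and labelled by
#' the mutational process they emulate: `SBS1` (clock-like C>T at NpCpG),
#' `SBS5` (broad, featureless), `SBS7a`/`SBS7b` (UV-driven C>T at
#' dipyrimidines, with 5'T vs 5'C emphasis respectively) and `flat`
#' (uniform background). These are synthetic stand-ins shaped like the
#' COSMIC v3 processes they are named after, not the COSMIC reference
#' columns; any COSMIC-format matrix can be supplied instead via
#' [read_signature_tsv()].
#'
#' @return A `signature_set`: list with `names` and a 96 x k matrix whose
#'   columns sum to 1.
#' @export
synthetic_signature_set <- function() {
  channels <- sbs_channels()
  sub <- sub(".*\\[(.*)\\].*", "\\1", channels)
  five <- substr(channels, 1, 1)
  three <- substr(channels, 7, 7)

  # deamination at methylated CpG: C>T with 3' G
  sbs1 <- ifelse(sub == "C>T" & three == "G", 0.80 / 4, 0.20 / 92)
  # broad clock-like spectrum dominated by T>C with 5' preference
  w5 <- c(A = 4, C = 2, G = 1, T = 3)[five]
  sbs5 <- ifelse(sub == "T>C", 0.50 * w5 / sum(w5[sub == "T>C"]),
          ifelse(sub == "C>T" & three != "G", 0.20 / 12, 0)) +
    ifelse(sub %in% c("C>A", "T>A", "T>G", "C>G"), 0.30 / 64, 0)
  # UV: C>T at dipyrimidines, 5'T-weighted (7a) vs 5'C-weighted (7b)
  sbs7a <- ifelse(sub == "C>T" & five == "T", 0.65 / 4,
           ifelse(sub == "C>T" & five == "C", 0.20 / 4,
           ifelse(sub == "C>T", 0.05 / 8, 0.10 / 80)))
  sbs7b <- ifelse(sub == "C>T" & five == "C", 0.65 / 4,
           ifelse(sub == "C>T" & five == "T", 0.20 / 4,
           ifelse(sub == "C>T", 0.05 / 8, 0.10 / 80)))
  flat <- rep(1, 96)

  m <- cbind(SBS1 = sbs1, SBS5 = sbs5, SBS7a = sbs7a, SBS7b = sbs7b, flat = flat)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- channels
  signature_set(m)
}

#' Construct a signature set from a 96 x k matrix
#'
#' @param m Matrix with 96 rows labelled by SBS channel and one column per
#'   signature; columns are renormalized to sum to 1 (must already be
#'   within 1e-3).
#' @return A `signature_set`.
#' @export
signature_set <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != 96) stop("signature matrix must have 96 rows")
  if (is.null(rownames(m))) stop("signature matrix must carry channel rownames")
  ord <- match(sbs_channels(), rownames(m))
  if (anyNA(ord)) stop("signature matrix rownames must be the 96 SBS channel labels")
  m <- m[ord, , drop = FALSE]
  if (any(m < 0)) stop("signature probabilities must be non-negative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-3)) stop("signature columns must sum to 1")
  m <- sweep(m, 2, cs, "/")
  structure(list(names = colnames(m), matrix = m), class = "signature_set")
}

#' Read / write a COSMIC-format signature TSV
#'
#' Rows are the 96 channels labelled `A[C>A]A`-style (any order), columns
#' are signatures; the first column holds the channel labels.
#'
#' @param path File path.
#' @return For the reader, a `signature_set`.
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  signature_set(m)
}

#' @rdname read_signature_tsv
#' @param sigset A `signature_set`.
#' @export
write_signature_tsv <- function(sigset, path) {
  df <- data.frame(Type = rownames(sigset$matrix), sigset$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Refit signature exposures by non-negative least squares
#'
#' The channel-normalized catalog is regressed on the signature matrix
#' under a non-negativity constraint; exposures are renormalized to sum to
#' 1 and the cosine similarity between catalog and reconstruction is
#' reported. Catalogs below `min_mutations` are too sparse for a stable
#' fit and are returned as indeterminate.
#'
#' @param catalog An `sbs_catalog` (or named 96-vector of counts).
#' @param sigset A `signature_set`.
#' @param min_mutations Minimum SNV count to attempt a fit (default 20).
#' @return An `exposure_vector` list: `sample_id`, `exposures` (named,
#'   summing to 1, or NA when indeterminate), `cosine`, `n_mutations`,
#'   `status` (`"ok"` or `"indeterminate"`).
#' @export
fit_exposures <- function(catalog, sigset, min_mutations = 20) {
  stopifnot(inherits(sigset, "signature_set"))
  v <- as.numeric(catalog)
  if (length(v) != 96) stop("catalog must have 96 channels")
  total <- sum(v)
  if (total == 0)
    stop("empty catalog: signature refitting requires at least one SNV; skip this sample")
  sid <- attr(catalog, "sample_id")
  if (is.null(sid)) sid <- NA_character_
  if (total < min_mutations) {
    return(structure(list(
      sample_id = sid,
      exposures = stats::setNames(rep(NA_real_, length(sigset$names)), sigset$names),
      cosine = NA_real_, n_mutations = total, status = "indeterminate"
    ), class = "exposure_vector"))
  }
  m <- v / total
  w <- pracma::lsqnonneg(sigset$matrix, m)$x
  recon <- as.numeric(sigset$matrix %*% w)
  cosine <- sum(m * recon) / (sqrt(sum(m^2)) * sqrt(sum(recon^2)))
  exposures <- if (sum(w) > 0) w / sum(w) else w
  structure(list(
    sample_id = sid,
    exposures = stats::setNames(exposures, sigset$names),
    cosine = min(1, cosine), n_mutations = total, status = "ok"
  ), class = "exposure_vector")
}

#' Samples eligible for signature analysis
#'
#' Signature refitting is restricted to TMB-high samples (TMB >= 10
#' mut/Mb, inclusive).
#'
#' @param tmb_results data.frame from [compute_tmb()].
#' @return Character vector of sample ids.
#' @export
select_signature_samples <- function(tmb_results) {
  tmb_results$sample_id[tmb_results$tmb_high]
}
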