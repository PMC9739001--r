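#' Write annotated variants to a VCF 4.2 file
#'
#' One multi-sample VCF; each record carries GENE/CSQ/POP_AF/CLASS INFO
#' annotations and per-sample DP:AD genotype fields (missing for samples
#' the record does not belong to).
#'
#' @param variants data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `pop_af`, `depth`, `alt_depth`,
#'   `pathogenicity_class`, `sample_id`.
#' @param path Output path.
#' @param samples Sample column order (default: sorted ids in `variants`).
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, samples = NULL, contig_lengths = NULL) {
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=angioscape",
    if (!is.null(contig_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths)),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=POP_AF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Pathogenicity class 1-5 or unknown\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  if (nrow(variants)) {
    v <- variants[order(variants$contig, variants$pos, variants$sample_id), ]
    info <- sprintf("GENE=%s;CSQ=%s;POP_AF=%s;CLASS=%s",
                    ifelse(is.na(v$gene) | v$gene == "", ".", v$gene),
                    v$consequence,
                    formatC(ifelse(is.na(v$pop_af), 0, v$pop_af),
                            format = "g", digits = 6),
                    v$pathogenicity_class)
    gt <- matrix(".", nrow(v), length(samples),
                 dimnames = list(NULL, samples))
    own <- sprintf("%d:%d,%d", v$depth, v$depth - v$alt_depth, v$alt_depth)
    gt[cbind(seq_len(nrow(v)), match(v$sample_id, samples))] <- own
    body <- paste(v$contig, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                  "DP:AD", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an annotated VCF into per-sample variant records
#'
#' Accepts any VCF carrying GENE/CSQ/POP_AF/CLASS INFO keys and DP/AD
#' FORMAT fields. Multi-allelic records are decomposed into one record
#' per alternate allele; a record is attributed to every sample with a
#' non-missing genotype field.
#'
#' @param path VCF path.
#' @param info_keys Named list remapping the INFO key names
#'   (`gene`, `consequence`, `pop_af`, `class`).
#' @return data.frame of variant records.
#' @export
read_vcf <- function(path,
                     info_keys = list(gene = "GENE", consequence = "CSQ",
                                      pop_af = "POP_AF", class = "CLASS")) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), consequence = character(0),
                      pop_af = numeric(0), depth = integer(0),
                      alt_depth = integer(0),
                      pathogenicity_class = character(0),
                      sample_id = character(0))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) return(empty)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gene <- vcfR::extract.info(vcf, info_keys$gene)
  csq <- vcfR::extract.info(vcf, info_keys$consequence)
  pop_af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, info_keys$pop_af)))
  cls <- vcfR::extract.info(vcf, info_keys$class)
  dp <- vcfR::extract.gt(vcf, "DP")
  ad <- vcfR::extract.gt(vcf, "AD")
  samples <- colnames(dp)
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    has <- which(!is.na(dp[i, ]) & dp[i, ] != ".")
    if (!length(has)) next
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    per <- lapply(has, function(j) {
      adv <- suppressWarnings(as.integer(strsplit(ad[i, j], ",", fixed = TRUE)[[1]]))
      altd <- adv[-1]
      if (length(altd) < length(alts)) altd <- rep_len(altd, length(alts))
      data.frame(contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                 ref = fix$REF[i], alt = alts,
                 gene = if (is.na(gene[i]) || gene[i] == ".") NA_character_ else gene[i],
                 consequence = csq[i],
                 pop_af = if (is.na(pop_af[i])) 0 else pop_af[i],
                 depth = as.integer(dp[i, j]),
                 alt_depth = altd[seq_along(alts)],
                 pathogenicity_class = cls[i],
                 sample_id = samples[j], stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Read/write the per-sample per-gene coverage matrix
#'
#' TSV with a `sample_id` column followed by one column per gene.
#'
#' @param coverage Samples x genes numeric matrix.
#' @param path File path.
#' @return Reader: the matrix with sample rownames.
#' @export
write_coverage_tsv <- function(coverage, path) {
  df <- data.frame(sample_id = rownames(coverage), coverage,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @export
read_coverage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Read/write the immune-density table
#' @param densities data.frame with `sample_id` and marker columns.
#' @param path File path.
#' @export
write_density_tsv <- function(densities, path) {
  utils::write.table(densities, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_tsv
#' @export
read_density_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read/write sample metadata
#' @param meta Sample metadata data.frame.
#' @param path File path.
#' @export
write_metadata_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_meta(df)
}
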