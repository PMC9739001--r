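#' Canonical DNA-damage-response gene list
#'
#' The 14-gene DNA-damage-response (DDR) set used to flag DDR-mutated
#' tumors throughout the package. Mutation of any of these genes (likely
#' pathogenic, class 4/5) marks a sample as DDR-positive.
#'
#' @return Character vector of 14 gene symbols.
#' @export
ddr_gene_set <- function() {
  c("ATM", "ATRX", "BRIP1", "CHEK2", "ERCC2", "ERCC3", "ERCC4", "ERCC5",
    "FANCF", "FANCI", "MSH2", "MSH3", "TP53", "XRCC2")
}

#' Fixed gene sets consulted across the pipeline
#'
#' @param ddr_genes DNA-damage-response genes; defaults to [ddr_gene_set()].
#' @param amplification_genes Genes recurrently amplified in secondary
#'   angiosarcoma that the simulator and reports track by name.
#' @param tsg_genes Tumor suppressor genes eligible for biallelic-state
#'   assessment; defaults to the DDR list (all of which act as tumor
#'   suppressors in this context).
#' @return A `gene_sets` list with case-normalized members.
#' @export
gene_sets <- function(ddr_genes = ddr_gene_set(),
                      amplification_genes = c("MYC", "FLT4", "CRKL"),
                      tsg_genes = ddr_gene_set()) {
  structure(list(
    ddr_genes = unique(toupper(ddr_genes)),
    amplification_genes = unique(toupper(amplification_genes)),
    tsg_genes = unique(toupper(tsg_genes))
  ), class = "gene_sets")
}

#' Clinical subgroup levels and their cluster
#'
#' Eight clinical subgroups: five primary (de novo) and three secondary.
#'
#' @return Named character vector mapping subgroup to cluster
#'   (`primary` / `secondary`).
#' @export
subgroup_cluster_map <- function() {
  c(soft_tissue = "primary", breast = "primary", skin_not_uv = "primary",
    visceral = "primary", heart = "primary",
    rt = "secondary", uv = "secondary", stewart_treves = "secondary")
}

#' @rdname subgroup_cluster_map
#' @export
subgroup_levels <- function() names(subgroup_cluster_map())

#' Validate sample metadata
#'
#' Checks the per-sample metadata table: unique ids, known subgroups, the
#' fixed subgroup-to-cluster mapping, and purity in (0, 1] where present.
#'
#' @param meta data.frame with columns `sample_id`, `cluster`, `subgroup`,
#'   `purity`.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
validate_sample_meta <- function(meta) {
  stopifnot(is.data.frame(meta),
            all(c("sample_id", "cluster", "subgroup", "purity") %in% names(meta)))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  map <- subgroup_cluster_map()
  bad <- setdiff(unique(meta$subgroup), names(map))
  if (length(bad)) stop("unknown subgroup(s): ", paste(bad, collapse = ", "))
  if (!all(meta$cluster == map[meta$subgroup]))
    stop("cluster does not match the fixed subgroup-to-cluster mapping")
  pur <- meta$purity[!is.na(meta$purity)]
  if (length(pur) && (any(pur <= 0) || any(pur > 1)))
    stop("purity must lie in (0, 1]")
  meta
}

.reduce_by_gene <- function(gr) {
  grl <- S4Vectors::split(gr, gr$gene)
  red <- GenomicRanges::reduce(grl)
  out <- unlist(red, use.names = FALSE)
  out$gene <- rep(names(red), S4Vectors::elementNROWS(red))
  out
}

#' Load a targeted-panel definition from a BED4 file
#'
#' Reads panel exons (BED 0-based half-open, 4th column = gene symbol),
#' merges overlapping intervals per gene, attaches intronic splice flanks,
#' and optionally a TERT promoter interval. The effective callable
#' territory (exons + splice flanks + TERT promoter, merged) defines the
#' denominator of tumor mutational burden.
#'
#' @param bed_path Path to a BED4 file.
#' @param splice_flank_bp Intronic bases on each side of an exon counted as
#'   splice-site region (default 2, the canonical splice dinucleotides).
#' @param tert_interval Optional list/vector with `contig`, `start`, `end`
#'   (1-based inclusive) delimiting the TERT promoter hotspot region.
#' @return A `panel_definition` with merged exon ranges, flanked ranges,
#'   the merged territory and `effective_size_mb`.
#' @export
load_panel <- function(bed_path, splice_flank_bp = 2, tert_interval = NULL) {
  if (!file.exists(bed_path)) stop("panel BED not found: ", bed_path)
  lines <- readLines(bed_path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (!length(lines) || all(!nzchar(lines))) stop("empty panel BED: ", bed_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4) stop("malformed BED line ", i, ": expected >= 4 columns")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop("malformed BED line ", i, ": non-numeric coordinates")
    if (s < 0 || e <= s) stop("malformed BED line ", i, ": need 0 <= start < end")
  }
  df <- data.frame(
    contig = vapply(fields, `[`, "", 1L),
    start0 = as.numeric(vapply(fields, `[`, "", 2L)),
    end0   = as.numeric(vapply(fields, `[`, "", 3L)),
    gene   = toupper(vapply(fields, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start0 + 1, df$end0),
                               gene = df$gene)
  build_panel(gr, splice_flank_bp = splice_flank_bp, tert_interval = tert_interval)
}

#' Construct a panel definition from exon ranges
#'
#' @param exons GRanges with a `gene` metadata column (1-based inclusive).
#' @inheritParams load_panel
#' @return A `panel_definition`.
#' @export
build_panel <- function(exons, splice_flank_bp = 2, tert_interval = NULL) {
  stopifnot(splice_flank_bp >= 0)
  exons <- .reduce_by_gene(exons)
  flanked <- .reduce_by_gene(exons + splice_flank_bp)
  tert <- NULL
  if (!is.null(tert_interval)) {
    ti <- as.list(tert_interval)
    tert <- GenomicRanges::GRanges(as.character(ti$contig),
                                   IRanges::IRanges(as.numeric(ti$start),
                                                    as.numeric(ti$end)))
  }
  terr <- GenomicRanges::granges(flanked)
  if (!is.null(tert))
    terr <- suppressWarnings(c(terr, GenomicRanges::granges(tert)))
  territory <- GenomicRanges::reduce(terr)
  structure(list(
    exons = exons,
    flanked = flanked,
    splice_flank_bp = splice_flank_bp,
    tert = tert,
    territory = territory,
    effective_size_mb = sum(GenomicRanges::width(territory)) / 1e6,
    genes = sort(unique(exons$gene))
  ), class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("Targeted panel:", length(x$genes), "genes,",
      length(x$exons), "merged exons,",
      sprintf("%.4f Mb effective territory", x$effective_size_mb),
      if (!is.null(x$tert)) "(incl. TERT promoter)" else "", "\n")
  invisible(x)
}

.overlaps_any <- function(q, subject) {
  if (is.null(subject) || length(subject) == 0) return(rep(FALSE, length(q)))
  suppressWarnings(IRanges::overlapsAny(q, subject))
}

#' Classify genomic positions against the panel territory
#'
#' Every position falls in exactly one category: `exonic` (inside a merged
#' exon), `splice` (within the splice flank but outside exons),
#' `tert_promoter` (inside the configured TERT promoter and not
#' exonic/splice), or `outside`. Unknown contigs map to `outside`.
#'
#' @param panel A `panel_definition`.
#' @param contig Character vector (recycled) of contig names.
#' @param pos 1-based positions.
#' @return Character vector of categories, one per position.
#' @export
in_territory <- function(panel, contig, pos) {
  stopifnot(inherits(panel, "panel_definition"))
  if (length(pos) == 0) return(character(0))
  if (any(pos < 1)) stop("positions must be >= 1")
  contig <- rep_len(as.character(contig), length(pos))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  out <- rep("outside", length(pos))
  exonic <- .overlaps_any(q, panel$exons)
  splice <- !exonic & .overlaps_any(q, panel$flanked)
  tert <- !exonic & !splice & .overlaps_any(q, panel$tert)
  out[tert] <- "tert_promoter"
  out[splice] <- "splice"
  out[exonic] <- "exonic"
  out
}

#' Write the merged panel exons back to BED4
#'
#' @param panel A `panel_definition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  ex <- panel$exons
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(ex)),
    start0 = GenomicRanges::start(ex) - 1,
    end0 = GenomicRanges::end(ex),
    gene = ex$gene
  )
  df <- df[order(df$contig, df$start0), ]
  writeLines(sprintf("%s\t%d\t%d\t%s", df$contig, df$start0, df$end0, df$gene), path)
  invisible(path)
}

#' Genes covered by a panel
#' @param panel A `panel_definition`.
#' @return Character vector of gene symbols.
#' @export
panel_genes <- function(panel) panel$genes

#' Exon ranges of one gene
#' @param panel A `panel_definition`.
#' @param gene Gene symbol.
#' @return GRanges of the gene's merged exons.
#' @export
gene_exons <- function(panel, gene) {
  panel$exons[panel$exons$gene == toupper(gene)]
}
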