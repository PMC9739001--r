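.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.density_defaults <- function() {
  # per-subgroup median (IQR) cell densities, cells/mm^2
  sg <- subgroup_levels()
  med <- rbind(
    CD3   = c(245, 234, 232, 362, 110, 355, 817, 588),
    CD8   = c(99, 78, 74, 140, 15, 101, 184, 87),
    FoxP3 = c(28, 14, 32, 14, 7, 32, 92, 23),
    CD4   = c(94, 127, 145, 150, 88, 190, 461, 457),
    CD20  = c(26, 22, 15, 67, 12, 21, 44, 88))
  iqr <- rbind(
    CD3   = c(549, 246, 280, 440, 204, 605, 862, 734),
    CD8   = c(406, 94, 60, 194, 71, 186, 230, 209),
    FoxP3 = c(63, 35, 50, 25, 27, 60, 161, 35),
    CD4   = c(137, 118, 143, 246, 107, 355, 460, 608),
    CD20  = c(82, 38, 11, 139, 34, 98, 145, 130))
  colnames(med) <- colnames(iqr) <- sg
  list(median = med, iqr = iqr)
}

.signature_mix_defaults <- function() {
  sg <- subgroup_levels()
  m <- matrix(0, length(sg), 5, dimnames = list(sg, c("SBS1", "SBS5", "SBS7a", "SBS7b", "flat")))
  base <- c(SBS1 = 0.30, SBS5 = 0.50, SBS7a = 0, SBS7b = 0, flat = 0.20)
  for (s in sg) m[s, ] <- base
  m["uv", ] <- c(0.10, 0.15, 0.40, 0.30, 0.05)
  m["skin_not_uv", ] <- c(0.25, 0.45, 0, 0, 0.30)
  m["visceral", ] <- c(0.45, 0.40, 0, 0, 0.15)
  m
}

#' Configuration of the synthetic angiosarcoma study
#'
#' Defaults reproduce the structure of the modeled study: an immunological
#' arm of 79 primary + 178 secondary samples and a genomic arm of 25 + 25,
#' spread over eight clinical subgroups; per-subgroup density medians and
#' IQRs; per-subgroup mutation-burden rates with a UV-dominant subgroup;
#' per-subgroup per-gene amplification probabilities (MYC-driven in
#' secondary tumors); and cluster-level DDR-mutation probabilities of
#' 0.24 (primary) and 0.60 (secondary).
#'
#' @param seed Master seed; every generator derives its stream from it.
#' @param ... Overrides for any default field (see the returned list).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 20221130, ...) {
  sg <- subgroup_levels()
  cfg <- list(
    seed = as.integer(seed),
    n_immune = stats::setNames(c(11, 20, 15, 28, 5, 126, 38, 14), sg),
    n_genomic = stats::setNames(c(4, 5, 4, 7, 5, 13, 7, 5), sg),
    density = .density_defaults(),
    nk_zero_prob = 0.6,
    nk_max = 30,
    tmb_rate = stats::setNames(c(1.8, 1.8, 3.2, 2.4, 0.8, 2.0, 8.5, 2.7), sg),
    tmb_sdlog = stats::setNames(c(0.4, 0.4, 0.8, 0.9, 0.4, 0.4, 0.6, 0.4), sg),
    signature_mix = .signature_mix_defaults(),
    amp_probs = list(
      breast = c(MYC = 0.20),
      skin_not_uv = c(MYC = 0.75),
      rt = c(MYC = 0.92, FLT4 = 0.31, CRKL = 0.08),
      uv = c(CRKL = 0.14),
      stewart_treves = c(MYC = 1.0)),
    amp_copies = 6:14,
    amp_min_expected_ratio = 3.3,
    ddr_mutation_probability = c(primary = 0.24, secondary = 0.60),
    driver_probability = c(primary = 1 - 0.20 / 0.76, secondary = 1 - 0.12 / 0.40),
    oncogene_pool = c("RASA1", "HNF1A", "PIK3CA", "PTPN11", "RAC1", "SETD2", "KDR"),
    loh_probability = 0.5,
    purity_range = c(0.30, 0.90),
    mean_depth = 500,
    n_common_germline_variants = 3,
    n_low_vaf_artifacts = 5,
    n_off_target_variants = 2,
    tert_promoter_probability = 0.1,
    synonymous_fraction = 0.30,
    coverage_depth_sdlog = 0.10,
    coverage_noise_sdlog = 0.02
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_simulation_config(cfg)
}

#' @rdname simulation_config
#' @param cfg A config list to validate.
#' @export
validate_simulation_config <- function(cfg) {
  sg <- subgroup_levels()
  stopifnot(all(sg %in% names(cfg$n_immune)), all(sg %in% names(cfg$n_genomic)))
  probs <- c(cfg$ddr_mutation_probability, cfg$driver_probability,
             cfg$loh_probability, cfg$nk_zero_prob,
             cfg$tert_promoter_probability, cfg$synonymous_fraction,
             unlist(cfg$amp_probs))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$density$median <= 0)) stop("density medians must be positive")
  if (any(cfg$density$iqr < 0)) stop("density IQRs must be non-negative")
  if (any(cfg$tmb_rate < 0)) stop("mutation-burden rates must be non-negative")
  rs <- rowSums(cfg$signature_mix)
  if (any(abs(rs - 1) > 1e-9)) stop("signature mixtures must sum to 1")
  if (cfg$purity_range[1] < 0.30)
    stop("genomic-arm purity must be at least 0.30")
  if (cfg$purity_range[2] > 1 || cfg$purity_range[1] > cfg$purity_range[2])
    stop("invalid purity range")
  cfg
}

#' Synthetic targeted-panel layout
#'
#' Deterministic 100-gene panel on one synthetic contig (`chrS`): the 14
#' DDR genes, the tracked amplification and oncogene targets, TERT (with a
#' 300 bp promoter interval upstream of its first exon), and filler genes.
#' Each gene has six 2.2 kb exons; total effective territory is about
#' 1.32 Mb, the scale of a large targeted oncology panel.
#'
#' @param splice_flank_bp Splice flank passed to [build_panel()].
#' @return A `panel_definition` with attributes `contig` and
#'   `genome_length` used by [synthetic_reference()].
#' @export
synthetic_panel <- function(splice_flank_bp = 2) {
  named <- c(ddr_gene_set(), "MYC", "FLT4", "CRKL", "RASA1", "HNF1A",
             "PIK3CA", "PTPN11", "RAC1", "SETD2", "KDR", "POT1", "TERT")
  filler <- sprintf("GENE%03d", seq_len(100 - length(named)))
  genes <- c(named, filler)
  n_exon <- 6; exon_w <- 2200; exon_step <- 2500; gene_step <- 16700
  gene_start <- 2000 + (seq_along(genes) - 1) * gene_step
  starts <- rep(gene_start, each = n_exon) +
    rep((seq_len(n_exon) - 1) * exon_step, times = length(genes))
  gr <- GenomicRanges::GRanges("chrS",
                               IRanges::IRanges(starts, width = exon_w),
                               gene = rep(genes, each = n_exon))
  tert_tss <- gene_start[match("TERT", genes)]
  tert <- list(contig = "chrS", start = tert_tss - 300, end = tert_tss - 1)
  panel <- build_panel(gr, splice_flank_bp = splice_flank_bp, tert_interval = tert)
  attr(panel, "contig") <- "chrS"
  attr(panel, "genome_length") <- max(gene_start) + gene_step
  panel
}

#' Synthetic reference sequence for the panel contig
#'
#' Uniform random bases, seeded; supplies the trinucleotide contexts the
#' variant simulator and catalog builder need, with no genome download.
#'
#' @param panel A panel from [synthetic_panel()] (or any panel carrying
#'   `contig`/`genome_length` attributes).
#' @param seed Seed for the base draw.
#' @return A [Biostrings::DNAStringSet] with one contig.
#' @export
synthetic_reference <- function(panel, seed = 1) {
  contig <- attr(panel, "contig")
  len <- attr(panel, "genome_length")
  if (is.null(contig) || is.null(len))
    stop("panel does not carry synthetic contig attributes")
  .with_seed(seed, function() {
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    dss <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(dss) <- contig
    dss
  })
}

#' Generate the sample sheet of one study arm
#'
#' @param config A [simulation_config()].
#' @param arm `"genomic"` (25 + 25 by default, with purity) or
#'   `"immunology"` (79 + 178 by default, purity NA).
#' @return Validated metadata data.frame with an `arm` column.
#' @export
generate_cohort <- function(config, arm = c("genomic", "immunology")) {
  arm <- match.arg(arm)
  n <- if (arm == "genomic") config$n_genomic else config$n_immune
  if (sum(n) == 0) stop("configuration yields zero samples")
  map <- subgroup_cluster_map()
  subgroup <- rep(names(n), times = n)
  prefix <- if (arm == "genomic") "AS_G" else "AS_I"
  meta <- data.frame(
    sample_id = sprintf("%s%03d", prefix, seq_along(subgroup)),
    cluster = unname(map[subgroup]),
    subgroup = subgroup,
    purity = NA_real_,
    arm = arm, stringsAsFactors = FALSE)
  if (arm == "genomic") {
    meta$purity <- .with_seed(config$seed + 101, function()
      round(stats::runif(nrow(meta), config$purity_range[1],
                         config$purity_range[2]), 3))
  }
  validate_sample_meta(meta)
}

.lognorm_sigma <- function(median, iqr) {
  # solve sigma from IQR = median * 2*sinh(z75 * sigma)
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

#' Generate immune-cell densities
#'
#' Marker densities are drawn from log-normal distributions whose median
#' equals the configured subgroup median and whose central 50% mass spans
#' the configured IQR (sigma solved in closed form from the IQR/median
#' ratio). NK-cell (CD56) counts are mostly zero with occasional small
#' values, never above `nk_max`.
#'
#' @param meta Sample metadata from [generate_cohort()].
#' @param config A [simulation_config()].
#' @return data.frame: `sample_id`, CD3, CD8, FoxP3, CD4, CD20, CD56.
#' @export
generate_densities <- function(meta, config) {
  if (any(config$density$median <= 0)) stop("density medians must be positive")
  markers <- rownames(config$density$median)
  .with_seed(config$seed + 103, function() {
    out <- data.frame(sample_id = meta$sample_id, stringsAsFactors = FALSE)
    for (mk in markers) out[[mk]] <- NA_real_
    out$CD56 <- NA_real_
    for (s in subgroup_levels()) {
      idx <- which(meta$subgroup == s)
      if (!length(idx)) next
      for (mk in markers) {
        med <- config$density$median[mk, s]
        sdl <- .lognorm_sigma(med, config$density$iqr[mk, s])
        out[[mk]][idx] <- round(stats::rlnorm(length(idx), log(med), sdl), 1)
      }
      zero <- stats::runif(length(idx)) < config$nk_zero_prob
      nk <- ifelse(zero, 0L, sample.int(config$nk_max, length(idx), replace = TRUE))
      out$CD56[idx] <- as.numeric(nk)
    }
    out
  })
}

# ---- variant generation internals ------------------------------------------

.base_codes <- function(genome, contig) {
  chars <- strsplit(as.character(genome[[contig]]), "", fixed = TRUE)[[1]]
  match(chars, c("A", "C", "G", "T")) - 1L
}

.trinuc_code <- function(codes, pos) {
  16L * codes[pos - 1L] + 4L * codes[pos] + codes[pos + 1L]
}

.code_of_string <- function(tri) {
  b <- match(strsplit(tri, "")[[1]], c("A", "C", "G", "T")) - 1L
  16L * b[1] + 4L * b[2] + b[3]
}

.channel_placement <- function() {
  # per channel: pyrimidine-strand trinuc/alt and their reverse complements
  channels <- sbs_channels()
  pyr_tri <- paste0(substr(channels, 1, 1), substr(channels, 3, 3),
                    substr(channels, 7, 7))
  pyr_alt <- substr(channels, 5, 5)
  data.frame(channel = channels,
             pyr_tri = pyr_tri, pyr_alt = pyr_alt,
             rc_tri = .revcomp(pyr_tri), rc_alt = .complement(pyr_alt),
             stringsAsFactors = FALSE)
}

.territory_context_index <- function(panel, genome) {
  contig <- attr(panel, "contig")
  if (is.null(contig)) contig <- as.character(
    GenomicRanges::seqnames(panel$territory))[1]
  codes <- .base_codes(genome, contig)
  len <- length(codes)
  terr <- panel$territory[as.character(GenomicRanges::seqnames(panel$territory)) == contig]
  inside <- logical(len)
  for (i in seq_along(terr)) {
    s <- max(2L, GenomicRanges::start(terr)[i])
    e <- min(len - 1L, GenomicRanges::end(terr)[i])
    if (s <= e) inside[s:e] <- TRUE
  }
  pos <- which(inside)
  tri <- .trinuc_code(codes, pos)
  list(contig = contig, codes = codes, len = len,
       pos_by_tri = split(pos, tri),
       outside_pos = setdiff(2:(len - 1L), pos))
}

.gene_lookup <- function(panel, len) {
  idx <- integer(len)
  fl <- panel$flanked
  genes <- unique(fl$gene)
  for (i in seq_along(fl)) {
    g <- match(fl$gene[i], genes)
    s <- max(1L, GenomicRanges::start(fl)[i])
    e <- min(len, GenomicRanges::end(fl)[i])
    idx[s:e] <- g
  }
  if (!is.null(panel$tert)) {
    s <- GenomicRanges::start(panel$tert); e <- GenomicRanges::end(panel$tert)
    tid <- match("TERT", genes)
    if (is.na(tid)) { genes <- c(genes, "TERT"); tid <- length(genes) }
    idx[s:e][idx[s:e] == 0L] <- tid
  }
  list(idx = idx, genes = genes)
}

.draw_base_not <- function(ref, n = length(ref)) {
  bases <- c("A", "C", "G", "T")
  vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
}

#' Generate somatic and nuisance variants for the genomic arm
#'
#' Per sample: a Poisson number of somatic passenger SNVs at the sample's
#' subgroup burden rate, with trinucleotide contexts drawn from the
#' subgroup's signature mixture and VAFs binomial around `purity / 2`;
#' cluster-probability DDR and oncogene driver mutations (class 4/5),
#' with designated loss-of-heterozygosity or second-hit events for tumor
#' suppressors; plus configured numbers of population-common germline
#' variants (popAF > 0.1%), low-VAF artifacts (VAF < 5%), and off-target
#' records, all labelled in the ground truth so filter tests can count
#' exact expected removals.
#'
#' @param meta Genomic-arm metadata.
#' @param panel A [synthetic_panel()].
#' @param config A [simulation_config()].
#' @param genome Reference from [synthetic_reference()].
#' @param sigset Signature set (default [synthetic_signature_set()]).
#' @return List with `variants` (data.frame) and `truth`
#'   (`samples` and `allelic` data.frames).
#' @export
generate_variants <- function(meta, panel, config, genome,
                              sigset = synthetic_signature_set()) {
  stopifnot(inherits(panel, "panel_definition"))
  if (!length(panel$exons)) stop("empty panel")
  ctx <- .territory_context_index(panel, genome)
  glk <- .gene_lookup(panel, ctx$len)
  place <- .channel_placement()
  mb <- panel$effective_size_mb
  chars <- c("A", "C", "G", "T")
  ref_at <- function(p) chars[ctx$codes[p] + 1L]
  gene_at <- function(p) {
    g <- glk$idx[p]
    ifelse(g == 0L, NA_character_, glk$genes[g])
  }
  ddr_in_panel <- intersect(ddr_gene_set(), panel$genes)
  onc_in_panel <- intersect(config$oncogene_pool, panel$genes)
  exon_pos <- lapply(stats::setNames(nm = c(ddr_in_panel, onc_in_panel)), function(g) {
    ex <- gene_exons(panel, g)
    unlist(mapply(seq, GenomicRanges::start(ex), GenomicRanges::end(ex),
                  SIMPLIFY = FALSE))
  })
  tert_pos <- if (!is.null(panel$tert))
    seq(GenomicRanges::start(panel$tert), GenomicRanges::end(panel$tert)) else integer(0)

  .with_seed(config$seed + 104, function() {
    all_var <- list(); truth_rows <- list(); allelic_rows <- list()
    for (k in seq_len(nrow(meta))) {
      sid <- meta$sample_id[k]; sg <- meta$subgroup[k]
      cl <- meta$cluster[k]; purity <- meta$purity[k]
      p_het <- purity / 2; p_loh <- purity / (2 - purity)
      rows <- list()

      emit <- function(pos, alt, consequence, class, pop_af, p_vaf,
                       ref = ref_at(pos), gene = gene_at(pos)) {
        n <- length(pos)
        depth <- stats::rpois(n, config$mean_depth)
        depth[depth < 1] <- 1L
        altd <- stats::rbinom(n, depth, p_vaf)
        altd[altd < 1] <- 1L
        data.frame(contig = ctx$contig, pos = pos, ref = ref, alt = alt,
                   gene = gene, consequence = consequence, pop_af = pop_af,
                   depth = depth, alt_depth = altd,
                   pathogenicity_class = class, sample_id = sid,
                   stringsAsFactors = FALSE)
      }

      # somatic passengers from the signature mixture
      rate <- stats::rlnorm(1, log(config$tmb_rate[sg]), config$tmb_sdlog[sg])
      n_som <- stats::rpois(1, rate * mb)
      if (n_som > 0) {
        mix <- config$signature_mix[sg, sigset$names]
        chan_p <- as.numeric(sigset$matrix %*% mix)
        chan <- sample.int(96, n_som, replace = TRUE, prob = chan_p)
        tab <- table(chan)
        for (ci in as.integer(names(tab))) {
          nk <- as.integer(tab[as.character(ci)])
          plus <- ctx$pos_by_tri[[as.character(.code_of_string(place$pyr_tri[ci]))]]
          minus <- ctx$pos_by_tri[[as.character(.code_of_string(place$rc_tri[ci]))]]
          pool <- c(plus, minus)
          if (!length(pool)) next
          sel <- pool[sample.int(length(pool), min(nk, length(pool)))]
          on_minus <- sel %in% minus & !(sel %in% plus)
          alt <- ifelse(on_minus, place$rc_alt[ci], place$pyr_alt[ci])
          syn <- stats::runif(length(sel)) < config$synonymous_fraction
          csq <- ifelse(syn, "synonymous", "missense")
          rows[[length(rows) + 1]] <- emit(sel, alt, csq, "3", 0, p_het)
        }
      }
      n_passenger <- sum(vapply(rows, nrow, integer(1)))

      # DDR driver (class 4/5 tumor suppressor hit)
      ddr_hit <- stats::runif(1) < config$ddr_mutation_probability[cl]
      ddr_gene <- NA_character_; ddr_mech <- NA_character_
      if (ddr_hit) {
        ddr_gene <- sample(ddr_in_panel, 1)
        biallelic_forced <- ddr_gene == "TP53"
        mech <- if (biallelic_forced) {
          sample(c("second_hit", "loh"), 1)
        } else if (stats::runif(1) < config$loh_probability) "loh" else "none"
        ddr_mech <- mech
        n_hits <- if (mech == "second_hit") 2L else 1L
        p_vaf <- if (mech == "loh") p_loh else p_het
        pos <- sample(exon_pos[[ddr_gene]], n_hits)
        rows[[length(rows) + 1]] <- emit(
          pos, .draw_base_not(ref_at(pos)),
          sample(c("missense", "nonsense"), n_hits, replace = TRUE, prob = c(0.7, 0.3)),
          sample(c("4", "5"), n_hits, replace = TRUE), 0, p_vaf,
          gene = ddr_gene)
        allelic_rows[[length(allelic_rows) + 1]] <- data.frame(
          sample_id = sid, gene = ddr_gene,
          true_state = if (mech == "none") "monoallelic" else "biallelic",
          mechanism = mech, stringsAsFactors = FALSE)
      }

      # non-DDR oncogene driver
      n_driver <- 0L
      if (stats::runif(1) < config$driver_probability[cl]) {
        g <- sample(onc_in_panel, 1)
        pos <- sample(exon_pos[[g]], 1)
        rows[[length(rows) + 1]] <- emit(
          pos, .draw_base_not(ref_at(pos)), "missense",
          sample(c("4", "5"), 1), 0, p_het, gene = g)
        n_driver <- 1L
      }

      # TERT promoter variant
      n_tert <- 0L
      if (length(tert_pos) && stats::runif(1) < config$tert_promoter_probability) {
        pos <- sample(tert_pos, 1)
        rows[[length(rows) + 1]] <- emit(pos, .draw_base_not(ref_at(pos)),
                                         "promoter", "3", 0, p_het)
        n_tert <- 1L
      }

      # population-common germline variants (fail the population rule)
      n_germ <- config$n_common_germline_variants
      if (n_germ > 0) {
        pool <- unlist(ctx$pos_by_tri, use.names = FALSE)
        pos <- sample(pool, n_germ)
        af <- round(10^stats::runif(n_germ, log10(0.002), log10(0.3)), 5)
        rows[[length(rows) + 1]] <- emit(
          pos, .draw_base_not(ref_at(pos)),
          sample(c("missense", "synonymous"), n_germ, replace = TRUE),
          sample(c("1", "2"), n_germ, replace = TRUE), af, 0.5)
      }

      # low-VAF artifacts (fail the VAF rule)
      n_art <- config$n_low_vaf_artifacts
      if (n_art > 0) {
        pool <- unlist(ctx$pos_by_tri, use.names = FALSE)
        pos <- sample(pool, n_art)
        depth <- stats::rpois(n_art, config$mean_depth)
        depth[depth < 21] <- 21L
        v <- stats::runif(n_art, 0.005, 0.04)
        altd <- pmax(1L, pmin(as.integer(round(depth * v)),
                              as.integer(ceiling(depth * 0.05)) - 1L))
        rows[[length(rows) + 1]] <- data.frame(
          contig = ctx$contig, pos = pos, ref = ref_at(pos),
          alt = .draw_base_not(ref_at(pos)), gene = gene_at(pos),
          consequence = "missense", pop_af = 0, depth = depth,
          alt_depth = altd, pathogenicity_class = "unknown",
          sample_id = sid, stringsAsFactors = FALSE)
      }

      # off-target records (fail the territory rule)
      n_off <- config$n_off_target_variants
      if (n_off > 0) {
        pos <- sample(ctx$outside_pos, n_off)
        rows[[length(rows) + 1]] <- emit(pos, .draw_base_not(ref_at(pos)),
                                         "other", "unknown", 0, 0.5)
      }

      sv <- do.call(rbind, rows)
      true_eligible <- sum(!sv$pathogenicity_class %in% c("1", "2", "unknown"))
      all_var[[k]] <- sv
      truth_rows[[k]] <- data.frame(
        sample_id = sid, subgroup = sg, cluster = cl, purity = purity,
        tmb_rate = rate, n_passenger = n_passenger,
        ddr_mutated = ddr_hit, ddr_gene = ddr_gene, ddr_mechanism = ddr_mech,
        n_driver = n_driver, n_tert = n_tert,
        n_germline = n_germ, n_artifact = n_art, n_off_target = n_off,
        true_eligible = true_eligible, true_tmb = true_eligible / mb,
        stringsAsFactors = FALSE)
    }
    list(variants = do.call(rbind, all_var),
         truth = list(samples = do.call(rbind, truth_rows),
                      allelic = if (length(allelic_rows))
                        do.call(rbind, allelic_rows)
                      else data.frame(sample_id = character(0),
                                      gene = character(0),
                                      true_state = character(0),
                                      mechanism = character(0))))
  })
}

#' Generate the per-sample per-gene coverage matrix
#'
#' Unamplified genes: coverage = baseline weight x per-sample depth factor
#' x multiplicative noise. Amplified genes are additionally scaled by the
#' purity mixture `1 - purity + purity * copies / 2`, so median-ratio
#' normalization recovers the expected relative coverage.
#'
#' @param meta Genomic-arm metadata.
#' @param panel A `panel_definition` (defines the gene list).
#' @param config A [simulation_config()].
#' @return List with `coverage` (samples x genes matrix) and
#'   `amplifications` truth data.frame (`sample_id`, `gene`, `copies`,
#'   `expected_ratio`).
#' @export
generate_coverage <- function(meta, panel, config) {
  genes <- panel_genes(panel)
  .with_seed(config$seed + 105, function() {
    cov <- matrix(NA_real_, nrow(meta), length(genes),
                  dimnames = list(meta$sample_id, genes))
    amp_rows <- list()
    for (k in seq_len(nrow(meta))) {
      sg <- meta$subgroup[k]; purity <- meta$purity[k]
      depth_factor <- stats::rlnorm(1, 0, config$coverage_depth_sdlog)
      base <- config$mean_depth * depth_factor *
        stats::rlnorm(length(genes), 0, config$coverage_noise_sdlog)
      scale <- rep(1, length(genes))
      probs <- config$amp_probs[[sg]]
      if (!is.null(probs)) {
        for (g in names(probs)) {
          if (!g %in% genes) next
          if (stats::runif(1) < probs[[g]]) {
            copies <- sample(config$amp_copies, 1)
            # amplification events are defined by the study as relative
            # coverage >= 3, so emitted events sit above the calling
            # threshold at the sample's purity
            floor_copies <- ceiling(
              2 * (config$amp_min_expected_ratio - (1 - purity)) / purity)
            copies <- max(copies, floor_copies)
            er <- expected_relative_coverage(copies, purity)
            scale[match(g, genes)] <- er
            amp_rows[[length(amp_rows) + 1]] <- data.frame(
              sample_id = meta$sample_id[k], gene = g, copies = copies,
              expected_ratio = er, stringsAsFactors = FALSE)
          }
        }
      }
      cov[k, ] <- round(base * scale, 2)
    }
    amps <- if (length(amp_rows)) do.call(rbind, amp_rows) else
      data.frame(sample_id = character(0), gene = character(0),
                 copies = integer(0), expected_ratio = numeric(0))
    list(coverage = cov, amplifications = amps)
  })
}
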