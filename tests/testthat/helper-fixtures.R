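# Shared fixtures, built in code at test time.

# two-gene toy panel: GENEA chrT:101-200,301-400; GENEB chrT:1001-1300
toy_panel <- function(splice_flank_bp = 2, tert = NULL) {
  gr <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(101, 301, 1001), c(200, 400, 1300)),
    gene = c("GENEA", "GENEA", "GENEB"))
  build_panel(gr, splice_flank_bp = splice_flank_bp, tert_interval = tert)
}

toy_panel_tert <- function(splice_flank_bp = 2) {
  toy_panel(splice_flank_bp,
            tert = list(contig = "chrT", start = 2001, end = 2300))
}

# variant record with overridable fields
make_variant <- function(contig = "chrT", pos = 150, ref = "C", alt = "T",
                         gene = "GENEA", consequence = "missense",
                         pop_af = 0, depth = 500, alt_depth = 150,
                         pathogenicity_class = "3", sample_id = "S1") {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, pop_af = pop_af, depth = depth,
             alt_depth = alt_depth, pathogenicity_class = pathogenicity_class,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# one full synthetic study, simulated once per test session and reused
.study_env <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (is.null(.study_env$dir)) {
    d <- file.path(tempdir(), "angioscape-study-fixture")
    as_simulate(d, simulation_config(seed = 20221130))
    .study_env$dir <- d
  }
  .study_env$dir
}

analysis_fixture <- function() {
  if (is.null(.study_env$analysis)) {
    .study_env$analysis <- suppressMessages(as_analyze(study_fixture()))
  }
  .study_env$analysis
}

truth_fixture <- function() {
  jsonlite::read_json(file.path(study_fixture(), "ground_truth.json"),
                      simplifyVector = TRUE)
}

# brute-force two-sided Fisher oracle: direct binomial-coefficient
# enumeration of all tables with the observed margins
fisher_oracle <- function(tab) {
  n <- sum(tab); r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
  if (n == 0 || r1 %in% c(0, n) || c1 %in% c(0, n)) return(1)
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- choose(c1, supp) * choose(n - c1, r1 - supp) / choose(n, r1)
  p_obs <- pr[supp == tab[1, 1]]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# exact Mann-Whitney oracle by enumeration of all rank splits
mw_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  x <- c(a, b); r <- rank(x)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(na + nb, na)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
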