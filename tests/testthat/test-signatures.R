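toy_genome <- function(seq = NULL) {
  if (is.null(seq)) {
    # deterministic sequence with all contexts scattered
    set.seed(7)
    seq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                 collapse = "")
  }
  dss <- Biostrings::DNAStringSet(seq)
  names(dss) <- "chrT"
  dss
}

test_that("channel labels follow the substitution x flank layout", {
  ch <- sbs_channels()
  expect_length(ch, 96)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[96], "T[T>G]T")
  expect_false(anyDuplicated(ch) > 0)
})

test_that("pyrimidine-strand mapping handles both strands", {
  expect_equal(sbs_channel_of("C", "T", "ACA"), "A[C>T]A")
  expect_equal(sbs_channel_of("G", "A", "TGT"), "A[C>T]A")  # reverse complement
  expect_equal(sbs_channel_of("T", "G", "CTG"), "C[T>G]G")
  expect_equal(sbs_channel_of("A", "C", "CAG"), "C[T>G]G")
  expect_true(is.na(sbs_channel_of("C", "T", "ANA")))
})

test_that("strand collapse covers all 96 x 2 representations consistently", {
  # oracle: construct, for every channel, both the pyrimidine-strand SNV
  # and its reverse-complement representation; both must hit that channel
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rc <- function(x) paste(rev(strsplit(comp(x), "")[[1]]), collapse = "")
  for (ch in sbs_channels()) {
    ref <- substr(ch, 3, 3); alt <- substr(ch, 5, 5)
    ctx <- paste0(substr(ch, 1, 1), ref, substr(ch, 7, 7))
    expect_equal(sbs_channel_of(ref, alt, ctx), ch)
    expect_equal(sbs_channel_of(comp(ref), comp(alt), rc(ctx)), ch)
  }
})

test_that("catalogs conserve SNV counts and flag missing contexts", {
  g <- toy_genome("AACATTGCA")  # pos 4: context CAT; pos 7: TGC
  snvs <- data.frame(contig = "chrT", pos = c(4, 7), ref = c("A", "G"),
                     alt = c("G", "A"))
  cat96 <- build_catalog(snvs, g)
  expect_equal(sum(cat96), 2)
  expect_equal(unname(cat96["A[T>C]G"]), 1L)  # A>G at CAT -> rc ATG -> T>C
  expect_equal(unname(cat96["G[C>T]A"]), 1L)  # G>A at TGC -> rc GCA
  # position at the contig edge has no context and is skipped
  expect_warning(c2 <- build_catalog(
    data.frame(contig = "chrT", pos = 1, ref = "A", alt = "C"), g), "skipped")
  expect_equal(sum(c2), 0)
  expect_equal(sum(build_catalog(snvs[0, ], g)), 0)  # empty list -> zero catalog
})

test_that("signature set columns are stochastic and readable round-trip", {
  s <- synthetic_signature_set()
  expect_equal(dim(s$matrix), c(96L, 5L))
  expect_true(all(abs(colSums(s$matrix) - 1) < 1e-6))
  expect_true(all(s$matrix >= 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tsv(s, path)
  s2 <- read_signature_tsv(path)
  expect_equal(s2$names, s$names)
  expect_equal(s2$matrix, s$matrix, tolerance = 1e-9)
})

test_that("exact mixtures are recovered to machine precision", {
  s <- synthetic_signature_set()
  # catalog exactly proportional to SBS7a
  cat_a <- structure(round(s$matrix[, "SBS7a"] * 1e6), sample_id = "x")
  fit <- fit_exposures(cat_a, s, min_mutations = 20)
  expect_equal(unname(fit$exposures["SBS7a"]), 1.0, tolerance = 1e-4)
  expect_equal(fit$cosine, 1.0, tolerance = 1e-6)

  # noise-free 60/40 two-signature mixture
  mix <- 0.6 * s$matrix[, "SBS1"] + 0.4 * s$matrix[, "SBS7b"]
  fit <- fit_exposures(mix * 1e7, s)
  expect_equal(unname(fit$exposures[c("SBS1", "SBS7b")]), c(0.6, 0.4),
               tolerance = 1e-6)
  # brute-force grid oracle over two-signature mixtures
  grid <- seq(0, 1, by = 0.001)
  sse <- vapply(grid, function(w) {
    sum((mix / sum(mix) - (w * s$matrix[, "SBS1"] +
                             (1 - w) * s$matrix[, "SBS7b"]))^2)
  }, numeric(1))
  expect_equal(grid[which.min(sse)], 0.6, tolerance = 1e-3)
})

test_that("fit residual is zero whenever the catalog lies in the cone", {
  s <- synthetic_signature_set()
  set.seed(11)
  for (i in 1:5) {
    w <- stats::runif(5); w <- w / sum(w)
    catal <- as.numeric(s$matrix %*% w) * 1e6
    fit <- fit_exposures(catal, s)
    expect_equal(fit$cosine, 1, tolerance = 1e-9)
    expect_equal(unname(fit$exposures), w, tolerance = 1e-5)
  }
})

test_that("sparse and empty catalogs are handled explicitly", {
  s <- synthetic_signature_set()
  sparse <- structure(c(rep(1L, 10), rep(0L, 86)), sample_id = "y")
  fit <- fit_exposures(sparse, s, min_mutations = 20)
  expect_equal(fit$status, "indeterminate")
  expect_true(all(is.na(fit$exposures)))
  expect_error(fit_exposures(integer(96), s), "empty catalog")
})

test_that("signature-eligible samples use the inclusive TMB cutoff", {
  tmb <- data.frame(sample_id = c("a", "b", "c"),
                    tmb = c(9.9, 10.0, 25),
                    tmb_high = c(FALSE, TRUE, TRUE))
  expect_equal(select_signature_samples(tmb), c("b", "c"))
  expect_equal(select_signature_samples(tmb[0, ]), character(0))
})

test_that("exposure recovery from multinomial catalogs is accurate at 500 SNVs", {
  s <- synthetic_signature_set()
  set.seed(202)
  errs <- replicate(100, {
    sigs <- sample(s$names, 3)
    w <- as.numeric(stats::rgamma(3, 1)); w <- w / sum(w)
    p <- as.numeric(s$matrix[, sigs] %*% w)
    catal <- stats::rmultinom(1, 500, p)[, 1]
    fit <- fit_exposures(catal, s)
    truth <- stats::setNames(numeric(5), s$names); truth[sigs] <- w
    sqrt(mean((fit$exposures - truth)^2))
  })
  expect_lte(mean(errs), 0.05)
})
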