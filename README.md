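# angioscape

Immunogenomic profiling of angiosarcoma cohorts in R.

Angiosarcomas are rare, aggressive vascular sarcomas that split into
primary (de novo) tumors and secondary tumors arising after
radiotherapy, UV exposure or chronic lymphedema. Characterizing how the
two clusters differ — in tumor-infiltrating lymphocyte densities and in
genomic features such as DNA-damage-response (DDR) gene mutations, MYC
amplification and tumor mutational burden (TMB) — is what identifies the
subgroups most likely to benefit from immunotherapy. `angioscape`
implements that analysis as a reusable, tested pipeline for anyone
working with targeted-panel sequencing plus immune-density data from
such cohorts, and ships a seeded synthetic-cohort generator so the whole
pipeline runs and is testable without access to patient-level data.

## What it computes

* **Variant filtering** — the four-rule tumor-only cascade: outside
  panel territory (with a TERT-promoter exception), synonymous outside
  splice regions, population allele frequency > 0.1%, VAF < 5%;
  exhaustive rule evaluation with per-rule removal counts.
* **Total TMB** — TMB-eligible variants (synonymous included) per Mb of
  effective territory; TMB-high at the inclusive cutoff of 10 mut/Mb.
* **Amplification calling** — per-sample median-normalized relative
  coverage r; r ≥ 3 is an amplification; purity-corrected copy number
  c = (2r − 2(1 − ρ))/ρ from the mixture model r = (1 − ρ) + ρc/2.
* **Biallelic inactivation** — second hit → VAF binomial tests
  (heterozygous ρ/2 vs LOH ρ/(2 − ρ)) → nearby-SNP allele-fraction
  shift.
* **SBS signature refitting** — 96-channel pyrimidine-strand catalogs;
  non-negative least squares against a column-stochastic signature
  matrix; exposures and reconstruction cosine for TMB-high samples.
* **Cohort statistics** — two-sided Fisher exact tests
  (point-probability rule) on genomic features, Mann-Whitney U on
  densities, median/IQR tables, and a per-sample oncoprint-style
  integration table.

## Worked example

```r
library(angioscape)

# DDR-mutation prevalence, 6/25 primary vs 15/25 secondary:
fisher_exact_two_sided(matrix(c(6, 19, 15, 10), 2, 2, byrow = TRUE))
#> [1] 0.02086171

# a complete synthetic study: simulate -> analyze -> report
dir <- file.path(tempdir(), "study")
as_simulate(dir, simulation_config(seed = 1))
res <- as_analyze(dir)
as_report(dir)

nrow(res$integration)       # one row per genomic sample
#> [1] 50
sum(res$tmb$tmb_high)       # TMB-high tumors at the inclusive >= 10 cutoff
#> [1] 4

subset(res$prevalence$cluster, feature == "ddr_mutated",
       c(pct_primary, pct_secondary, p_value))
#>             pct_primary pct_secondary      p_value
#> ddr_mutated           8            60 0.0002097581
```

The simulated study lands where the modeled cohort structure says it
should: secondary tumors carry more DDR mutations and MYC
amplifications, CD3⁺ densities are higher in secondary tumors
(medians 255 vs 491 cells/mm² at seed 1, Mann-Whitney p ≈ 1e-4), and a
handful of UV-associated tumors are TMB-high with UV-signature-dominated
exposures. Individual percentages fluctuate with the seed — the genomic
arm has only 25 samples per cluster, so at seed 1 the primary-cluster
DDR draw came out 2/25 (8%) against a configured rate of 24%.

## Package layout

* `R/` — panel model, synthetic cohort generator, filtering, TMB, copy
  number, allelic state, signatures, statistics, pipeline orchestration.
* `vignettes/angioscape-methods.Rmd` — the methods vignette: models,
  assumptions, calibration choices, limitations.
* `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code).
* `inst/extdata/signatures_synthetic.tsv` — the bundled synthetic
  signature matrix in COSMIC TSV format.
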