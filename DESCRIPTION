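Package: angioscape
Title: Immunogenomic Profiling of Angiosarcoma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for combined immunological and genomic
    profiling of angiosarcoma cohorts split into primary (de novo) and
    secondary (radiotherapy-, UV- or lymphedema-associated) tumors.
    Implements targeted-panel somatic variant filtering, total tumor
    mutational burden, coverage-based amplification calling with tumor
    purity correction, biallelic-inactivation assessment of tumor
    suppressor genes, single-base-substitution mutational signature
    refitting by non-negative least squares, and cohort statistics
    (Fisher exact, Mann-Whitney U) over immune-cell densities and
    genomic features. A seeded synthetic-cohort generator emulating the
    primary/secondary study structure makes every stage testable
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
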