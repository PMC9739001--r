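---
title: "Methods: immunogenomic profiling of angiosarcoma cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunogenomic profiling of angiosarcoma cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioscape)
```

## Scope and data model

Angiosarcomas are rare vascular sarcomas split into two etiological
clusters — primary (de novo) tumors arising in soft tissue, breast,
non-UV skin, viscera or heart, and secondary tumors associated with prior
radiotherapy, UV exposure, or chronic lymphedema (Stewart-Treves). The
package analyzes such cohorts along two arms:

* an **immunological arm**: per-sample lymphocyte densities (cells/mm²)
  for CD3⁺, CD8⁺, FoxP3⁺, CD4⁺ T-cell subsets, CD20⁺ B cells and CD56⁺ NK
  cells, measured upstream by multiplex immunohistochemistry and consumed
  here as a table;
* a **genomic arm**: targeted-panel sequencing of tumors with at least
  30% tumor cells, yielding annotated small variants (VCF), per-gene mean
  coverages, and a tumor-purity estimate per sample.

Everything downstream is organized around five containers: the panel
definition (merged exon intervals plus splice flanks and a TERT promoter
interval), per-sample variant records, the coverage matrix, 96-channel
substitution catalogs, and the density table.

## Variant filtering

Tumor-only panel calls are filtered by four exclusion rules, evaluated
exhaustively so per-rule removal counts are exact:

1. positions outside exons and splice-site regions, except the TERT
   promoter (`R1`);
2. synonymous variants not in a splice-site region (`R2`);
3. population allele frequency strictly above 0.1% (`R3`);
4. variant allele frequency strictly below 5% (`R4`).

Both thresholds are strict inequalities, so boundary values (popAF
exactly 0.001, VAF exactly 0.05) survive; a missing population frequency
counts as 0 because absence from a population database is not evidence of
commonness. Zero-depth records are rejected as malformed rather than
attributed to `R4`. The *reportable* set passes all four rules; the
*TMB-eligible* set re-admits synonymous variants (total TMB counts
synonymous and non-synonymous mutations) and is derived from the same
outcome objects, which guarantees `reportable ⊆ tmb_eligible`.

The splice flank defaults to 2 intronic bases per exon side (the
canonical splice dinucleotides) and is configurable; the TERT promoter
interval is configurable and defaults, in the synthetic panel, to 300 bp
upstream of the TERT transcription start. Class-3 variants (unknown
significance) are TMB-eligible: TMB is class-agnostic here, an assumption
worth remembering when comparing against pipelines that count only
pathogenic calls.

## Tumor mutational burden

TMB is the count of TMB-eligible variants divided by the effective panel
territory in megabases. The denominator includes splice flanks and the
TERT promoter — exactly the territory whose variants are counted in the
numerator. TMB-high means TMB ≥ 10 mut/Mb, inclusive: a sample exactly at
the cutoff is high, and the same inclusive predicate selects samples for
signature analysis. No minimum-variant QC rule is applied; a sample with
zero eligible variants simply has TMB 0.

## Amplification calling and copy number

Per sample, gene coverages are divided by per-gene baseline weights
(default 1, standing in for a panel of normals) and normalized by the
per-sample median across genes; at least 10 genes are required for the
median to be meaningful. A relative coverage ratio ≥ 3 (inclusive) is an
amplification call. Copy number is estimated from the two-population
mixture of diploid stromal cells and tumor cells with \(c\) copies,

\[ r = (1-\rho) + \rho\,c/2 \quad\Longrightarrow\quad
   c = \frac{2r - 2(1-\rho)}{\rho}, \]

with purity \(\rho \in (0,1]\), floored at 0. The diploid-background
assumption mirrors the mixture correction itself; losses are not called.
Note the calling threshold interacts with purity: a gene at 8 copies in a
30%-pure tumor has an expected ratio of only 1.6 and is invisible to the
ratio-3 rule. This is a property of the method, not of the
implementation.

## Biallelic inactivation

For class-4/5 variants in tumor suppressor genes the package asks whether
one or both alleles are hit, using the evidence hierarchy second hit →
VAF → nearby SNPs:

1. two distinct class-4/5 variants in the gene → biallelic (second hit);
2. a one-sided binomial test rejects the heterozygous VAF model
   (expected VAF \(\rho/2\)) upward **and** the LOH model (expected VAF
   \(\rho/(2-\rho)\)) is not rejected → biallelic via LOH;
3. with ≥ 3 nearby heterozygous SNPs, a median allele-fraction shift from
   0.5 exceeding half the LOH-expected shift \(\rho/(2(2-\rho))\) →
   biallelic via SNP imbalance;
4. otherwise monoallelic.

Calls are indeterminate below 50× depth, with unknown purity, or when the
gene is amplified (the diploid VAF model then does not apply). The
decision rule itself — levels, directions, and the default test level
α = 0.05 — is this package's design; the evidence sources are standard.
At depth 500 the VAF test separates het from LOH reliably for purity
above roughly 0.4; below that the two expectations (\(\rho/2\) vs
\(\rho/(2-\rho)\)) are close and recall degrades gracefully toward
monoallelic, never toward spurious biallelic calls.

## Mutational signatures

Single-nucleotide variants of TMB-high samples are binned into the
standard 96 trinucleotide channels; purine-reference substitutions are
reverse-complemented onto the pyrimidine strand. Exposures are obtained
by non-negative least squares of the channel-normalized catalog on a
column-stochastic signature matrix, renormalized to sum to one, with the
cosine similarity of the reconstruction reported as fit quality. NNLS was
chosen because it is the standard deterministic refitting approach;
catalogs below 20 SNVs (configurable) are reported indeterminate, since
panel-scale catalogs this small cannot support a stable five-parameter
fit — on a ~1.3 Mb panel, TMB-high begins at ~14 SNVs, so indeterminate
TMB-high samples do occur and are reported as such rather than dropped.
A configurable exposure threshold (default 0.2) separates "detected" from
"no clear signature" in reports.

The bundled signature set is **synthetic**: five stand-in spectra shaped
like the processes they are named for — SBS1 (C>T at NpCpG), SBS5 (broad,
T>C-dominated), SBS7a/SBS7b (UV dipyrimidine C>T with 5'T vs 5'C
emphasis) and a flat background. They are built in code
(`synthetic_signature_set()`), are deliberately more mutually
distinguishable than the real COSMIC columns, and any COSMIC-format TSV
can be substituted via `read_signature_tsv()`. Restricting refitting to a
small subset rather than the full 60+ catalog avoids overfitting at panel
scale.

## Cohort statistics

Categorical genomic features (any pathogenic mutation, DDR-gene mutation,
any/per-gene amplification, TMB-high) are compared between clusters with
the two-sided Fisher exact test using the point-probability rule: the
p-value sums the probabilities of all tables with the observed margins
whose point probability does not exceed the observed one, with a 1e-12
relative tolerance on probability ties. Continuous densities are compared
with the Mann-Whitney U test: exact when \(n_a n_b \le 400\) without
ties, otherwise a normal approximation with tie and continuity
correction (the asymptotic convention of mainstream statistical
software). Summaries report medians and type-7 (linear interpolation)
IQRs; p-values are raw — no multiplicity adjustment — matching the
study design this package models. The per-sample integration table joins
TMB, per-gene mutation classes, amplifications, DDR status and densities,
restricting gene columns to genes altered in at least two samples (an
oncoprint-style recurrence filter; the full table is available with
`min_samples = 1`).

## The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions. Arm sizes are 79 primary / 178 secondary (immunology) and
25 / 25 (genomic, with Table-1-style subgroup counts). Choices that the
modeled study does not pin down were made once, on field-realism grounds:

* **Densities** are log-normal per subgroup and marker, parameterized so
  the distribution median equals the configured median and the central
  50% mass spans the configured IQR (\(\sigma =
  \operatorname{asinh}(\mathrm{IQR}/2m)/z_{0.75}\)); log-normality
  reflects the heavy right tails of infiltrate counts. NK densities are
  mostly zero, never above 30. A zero IQR degenerates to a point mass at
  the median.
* **Mutation burden**: per-sample passenger rates are log-normal around
  per-subgroup medians (UV ≫ others), counts Poisson at rate × panel Mb.
  The published per-subgroup TMB table does not exist, so rates are free
  calibration: they were set so that cluster TMB medians land near
  3.2 / 3.9 mut/Mb once driver and DDR hits are added on top of
  passengers.
* **Contexts** are drawn from the subgroup's signature mixture and placed
  only at genome positions carrying the required trinucleotide (either
  strand) inside the panel territory; the ~1.7 Mb reference contig is
  random sequence generated from the seed at run time.
* **VAFs** are binomial at the site depth (Poisson around 500×) with
  success probability \(\rho/2\), or \(\rho/(2-\rho)\) for designated LOH
  events; TP53 hits are always biallelic (second hit or LOH), other DDR
  hits are LOH with probability 0.5.
* **DDR and driver mutations** are cluster-level Bernoulli events
  (DDR: 0.24 primary / 0.60 secondary). Oncogene-driver probabilities
  were solved so the overall any-pathogenic fraction is ~0.80 / 0.88.
* **Amplifications** are per-subgroup per-gene Bernoulli events (MYC
  most prevalent in RT and Stewart-Treves subgroups) with copies drawn
  from 6–14 and floored at the purity-dependent level where the expected
  ratio is 3.3: observed amplification prevalences in the modeled study
  are prevalences of *called* events (ratio ≥ 3), so emitted events must
  sit above the calling threshold at the sample's purity. FLT4 and CRKL
  are independent per-gene events; the real co-occurrence of FLT4 with
  MYC is not enforced.
* **Nuisance records** — 3 population-common germline variants, exactly
  5 low-VAF artifacts and 2 off-target records per sample — are labelled
  in the ground truth so filter tests can count exact removals.

What the generator does **not** emulate: indels beyond trivial events,
structural variants, read-level sequencing error, FFPE artifact spectra,
subclonality, germline contamination beyond the popAF-common class, and
correlated immune/genomic features within a sample. Green tests therefore
demonstrate correctness of the pipeline's logic and statistics under the
declared generative model, not robustness to every failure mode of real
FFPE panel data.

## Numerical and reproducibility choices

All generators derive their streams from a single master seed (fixed
offsets per stage), making every emitted file byte-identical across runs
with the same configuration. Degenerate inputs are explicit: empty VCFs
produce TMB 0 for all samples; zero-margin contingency tables return
p = 1 with a message; zero catalogs are an error instructing the caller
to skip; all-zero coverage is an error. Problem sizes in the test suite
and acceptance script are the study's own (257 + 50 samples, ~1.3 Mb
panel, 100 simulated catalogs of 500 mutations), which keeps a full
simulate–analyze–report cycle under half a minute on one CPU.

## Known limitations

Tumor-only filtering cannot fully remove rare germline variants (no
matched normal); the copy-number model assumes a diploid background and
misses low-level amplifications at low purity; the allelic-state rule
assumes copy number 2 at the locus; the synthetic signature set is not
COSMIC and exposure values are not comparable across signature sets; and
the Mann-Whitney asymptotic p-values differ from exact ones in small
tied samples, as in any implementation following the asymptotic
convention.
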