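---
title: "Candidate-gene case-control association analysis with candgene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene case-control association analysis with candgene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(candgene)
library(dplyr)
```

## The analysis this package implements

`candgene` implements the full statistical workflow of a candidate-gene
case-control association study of biallelic SNPs, of the kind used to ask
whether variants in immune-regulatory genes (here the motivating panel is
five TNFAIP3 SNPs and four TNIP1 SNPs, with ankylosing spondylitis as the
case phenotype) shift disease risk. The stages, each exposed as a
data-frame-first function returning a tibble, are:

1. **Counting** (`count_genotypes()`): per-SNP genotype and allele counts by
   case-control group, complete-case per SNP.
2. **Quality control** (`hwe_test()`): Pearson chi-square test of
   Hardy-Weinberg equilibrium in controls.
3. **Association** (`allelic_test()`, `genotype_model_test()`,
   `adjusted_or()`, `stratified_test()`): odds ratios with Woolf confidence
   intervals under allelic, codominant, dominant and recessive codings,
   chi-square or Fisher P values, Bonferroni correction, and logistic models
   for covariate adjustment and stratification.
4. **Haplotypes** (`em_haplotypes()`, `ld_matrix()`,
   `haplotype_association()`): EM estimation of haplotype frequencies from
   unphased genotypes, pairwise D'/r², and haplotype-level 2×2 association.
5. **Risk score** (`wgrs_analysis()`): a weighted genetic risk score
   (risk-allele dosage × ln OR, summed), compared between groups by
   Mann-Whitney U, modelled per unit by logistic regression, and evaluated by
   ROC/AUC with a Youden-optimal operating point.
6. **Interaction** (`mdr_search()`): multifactor dimensionality reduction
   with stratified cross-validation and a permutation test.
7. **Orchestration** (`run_full_analysis()`): all of the above with TSV/JSON
   reports.

A seeded generator (`simulate_cohort()`, `tnfaip3_panel_config()`) creates
cohorts with the statistical structure the analysis assumes, so every stage
is testable without access to individual-level data.

## Statistical model and conventions

**Alleles and orientation.** Each SNP is biallelic; the *minor* allele is the
rarer allele in the pooled case+control sample, with frequency ties broken
toward the lexicographically smaller base. All odds ratios are oriented
minor-vs-major, so OR < 1 means the minor allele is protective.

**Odds ratios.** The OR of a 2×2 table is the cross-product `ad/bc`; its 95%
CI is the Woolf (log-scale Wald) interval
`exp(log OR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero the
Haldane-Anscombe correction adds 0.5 to every cell and the result is flagged
`corrected`; a table with an all-zero row or column has no defined OR and is
an error. This choice reproduces printed ORs and CIs of published studies of
this design; profile or exact CIs are deliberately not the default.

**Test selection.** The 2×2 (or 2×3) P value is the Pearson chi-square
without continuity correction, switching to Fisher's exact test when any
*expected* cell is below 5. The threshold is configurable
(`fisher_threshold`) and the chosen method is always reported in the
`method` column. With expected cells of exactly 5 or more the chi-square is
kept — on the motivating panel that rule keeps the chi-square branch for the
rarest informative SNP (expected minor cells of 6) and matches the printed
P values.

**HWE.** The Hardy-Weinberg test compares observed genotype counts with
`n·(p², 2pq, q²)` at the observed allele frequency, as a 1-df chi-square
without continuity correction; monomorphic SNPs return chi-square 0, P = 1,
flagged. The chi-square (rather than exact) test is used because it is the
standard reported alongside this design and it reproduces published HWE
columns exactly.

**Multiple testing.** `bonferroni(p, m)` maps each P to `min(1, m·p)`. The
family size defaults to the number of SNPs in the panel (nine in the
motivating design) and is applied separately per comparison type, matching
the per-row corrected-P columns of published tables.

**Covariate adjustment and stratification.** Adjusted ORs come from
maximum-likelihood logistic regression (`stats::glm`) of status on a genotype
contrast plus covariates (default sex and age), with Wald CIs. Complete
separation and non-convergence are errors, not silent results.
`stratified_test()` follows the patients-vs-controls convention of clinical
stratifications: for sex and age both arms are restricted to the stratum;
for HLA-B27, BASDAI and BASFI — attributes measured only in patients — the
cases are restricted while **all** controls serve as the comparison group in
every stratum. Age is dichotomised at 29 years and BASDAI/BASFI at 4 (the
conventional activity/function cutoffs), all configurable.

## EM haplotype estimation

For a set of 2–8 loci, `em_haplotypes()` maximises the multinomial
likelihood of the unphased genotype classes under random mating. The E step
distributes each multi-heterozygote over its `2^(h-1)` consistent phase
pairs in proportion to the current haplotype-frequency products; the M step
re-estimates frequencies from expected counts; iteration stops when the
log-likelihood gain drops below `tol = 1e-8` (default) or after `max_iter =
1000` iterations (non-convergence is flagged, never silently ignored). The
log-likelihood is checked to be non-decreasing at every iteration, and at
the fixed point the implied allele frequencies equal the sample allele
frequencies.

Initialisation is the uniform distribution — fully deterministic. Uniform
initialisation is an exact fixed point of the EM map whenever the data leave
phase completely unidentified (a lone double heterozygote stays at the
symmetric 0.25/0.25/0.25/0.25 solution, which is the honest summary of such
data), but on some small panels that symmetry makes the uniform start a
saddle that EM cannot leave. `n_starts > 1` therefore adds seeded
multiplicative jitter around the uniform start and keeps the best final
log-likelihood; the test suite verifies that with a handful of restarts the
EM attains the global optimum found by exhaustive simplex search on small
panels. Haplotypes with more than 8 loci are refused outright (the
`2^k` state space and `4^k` pair space stop being meaningful for a
candidate-gene panel well before that).

**LD statistics.** From two-locus haplotype frequencies,
`D = p_AB − p_A·p_B`, `D' = |D|/D_max` with the usual sign-dependent
`D_max`, and `r² = D²/(p_A p_a p_B p_b)`. Only the range bounds `0 ≤ D' ≤ 1`
and `0 ≤ r² ≤ 1` are invariants; `r²` is not bounded by `D'²` in general.

**Haplotype association** uses the EM-expected chromosome counts
(`frequency × 2N`, fractional) directly in the 2×2, Haploview-style.
Haplotypes with pooled frequency below 0.03 are dropped by default — chosen
because published tables of this design list no haplotype rarer than ~0.034
— and the threshold is configurable. Because the counts are fractional, the
haplotype P value is always the chi-square; an exact test on expected counts
would be a category error.

## The weighted genetic risk score

Each scored SNP contributes `(risk-allele count 0..2) × ln(OR)`. Protective
SNPs (OR < 1) are flipped: their risk allele is the major allele and the
weight is `|ln OR|`, so all weights are non-negative. The orientation is a
presentation choice only — flipping every SNP reverses the score direction,
mapping AUC to 1−AUC and leaving |Z| unchanged, which the tests assert.
Weights default to the ORs estimated from the input data itself (as studies
of this design typically do); externally estimated weights can be supplied.

The score is evaluated three ways, and their consistency is itself an
invariant: the Mann-Whitney U (mid-ranks, tie-corrected normal
approximation, two-sided P), the per-unit logistic OR, and the empirical ROC
curve whose AUC equals `U/(n₁n₀)` identically — tie conventions are aligned
by construction. The AUC CI uses the Hanley-McNeil standard error; the
operating point maximises Youden's J = sensitivity + specificity − 1 with
ties broken toward the lower threshold. Individuals missing any scored
genotype are excluded and listed, never imputed.

## MDR conventions

`mdr_search()` uses the canonical MDR settings: 10-fold cross-validation
stratified by status; a genotype cell is high-risk iff its training
case:control ratio is at least the training split's overall ratio (ties
high-risk; cells empty in training are low-risk); fitness is testing
*balanced* accuracy, robust to any case:control imbalance; the best
combination per order k is the one with the highest mean testing balanced
accuracy, reported with its cross-validation consistency (folds in which it
was the fold-best) and a permutation P from full-search label permutations
(default 1000, seeded). The enumeration is exhaustive — `choose(p, k)`
combinations — which is the method's point at candidate-gene scale.

## The synthetic-cohort generator

`simulate_cohort()` draws the cohort the analysis assumes:

* **Controls** are in HWE at the configured minor-allele frequencies; SNPs
  in an LD block are built from two haplotypes drawn from the block's
  haplotype distribution.
* **Cases** follow a multiplicative allele-level risk model: the case allele
  frequency is `q' = OR·q / (1 − q + OR·q)`, which preserves HWE within
  cases and makes the *allelic* OR the generative parameter — chosen because
  allelic ORs are what this study design reports. Genotype-level ORs then
  hold only approximately, which downstream tests must (and do) tolerate.
  For LD blocks the case haplotype distribution is the multiplicative tilt
  of the control distribution fitted by iterative proportional fitting, so
  every member SNP hits its target case allele frequency exactly while the
  block's interaction structure is preserved.
* **Covariates** are drawn independently of genotype (the motivating study
  reports no genotype-covariate association): sex and age per arm, HLA-B27
  status in cases, and right-skewed gamma-distributed BASDAI/BASFI clipped
  to the 0–10 scale in cases, with controls left missing as for typical
  healthy volunteers. A `confounding` knob ties one SNP's allele frequency
  to sex on the logit scale, used to test that adjustment de-biases the
  crude OR.
* **Determinism**: the seed in the config fully determines the cohort; the
  generator restores the caller's RNG state.

`tnfaip3_panel_config()` bundles the motivating nine-SNP design: 667 cases /
667 controls; control MAFs 0.004–0.25 and allelic ORs 0.62–1.40 as published;
two TNFAIP3 LD pairs and the TNIP1 triple with haplotype frequencies chosen
to be exactly consistent with the published control MAFs and as close as
arithmetic allows to the published control haplotype frequencies. Two
judgment calls, fixed once:

* One SNP's minor allele was entirely absent from the published controls; a
  control MAF of 0 is outside the generator's domain, so the template gives
  it control MAF 2/1334 with OR 2.5, reproducing the published *case*
  carrier count in expectation. The published "OR" for that SNP is not a
  cross-product OR and is not imitated.
* The published haplotype table and LD figure are not perfectly consistent
  with each other: the haplotype frequencies implied by the published
  tables give closed-form D' ≈ 0.98 but r² ≈ 0.44 at the strongest TNFAIP3
  pair, slightly above the figure's "r² < 0.4". The template follows the
  tables (exact MAF consistency wins); tests assert the D' regime.

What the generator does **not** emulate: coalescent realism, recombination,
population structure, relatedness, genotyping error, or any
genotype-covariate correlation beyond the explicit confounding knob. Passing
tests on simulated cohorts therefore demonstrate the estimators' statistical
correctness under the stated model, not robustness to real-data artefacts.

## A worked example

```{r example}
cfg <- tnfaip3_panel_config(seed = 20260924)
cohort <- simulate_cohort(cfg)
counts <- count_genotypes(cohort$genotypes, cohort$phenotypes)

# QC + association
hwe_test(counts, "control") %>% select(snp_id, chisq, p_hwe, monomorphic)
allelic_test(counts) %>% select(snp_id, or, ci_low, ci_high, p, p_bonferroni)

# haplotypes and LD over one published block
em <- em_haplotypes(cohort$genotypes, c("rs13207033", "rs10499194"),
                    pheno = cohort$phenotypes)
tidy(em)
haplotype_association(em)
ld_matrix(cohort$genotypes, c("rs13207033", "rs10499194"))

# weighted genetic risk score over the TNFAIP3 SNPs
tnfaip3 <- cfg$snps$snp_id[cfg$snps$gene == "TNFAIP3"]
prof <- wgrs_analysis(cohort$genotypes, cohort$phenotypes, snps = tnfaip3)
glance(prof)

# MDR interaction search (light settings for the vignette)
mdr <- mdr_search(cohort$genotypes, cohort$phenotypes, k_range = 1:2,
                  n_perm = 100, seed = 1)
tidy(mdr)
```

The association stages also run without individual-level data, from a
genotype-counts table such as the bundled published panel:

```{r counts-only}
published_panel_counts() %>%
  allelic_test() %>%
  select(snp_id, or, ci_low, ci_high, p, p_bonferroni)
```

## Numerical choices and degenerate inputs

* Chi-square tests never use a continuity correction (matching the printed
  P values this design reports); the Fisher switch covers the
  small-expected-count regime instead.
* `odds_ratio()` accepts fractional counts so the haplotype stage can test
  EM-expected counts; integrality is required only for Fisher's exact test.
* Monomorphic SNPs: NA association rows (not errors), HWE P = 1, NA LD.
* An empty genotype class makes only that model comparison NA; the others
  proceed.
* Logistic separation raises an error recommending exact methods rather
  than returning a meaningless Wald CI.
* EM tolerance 1e-8 on the log-likelihood, max 1000 iterations, uniform
  deterministic start, optional seeded multi-start as discussed above.
* All Monte-Carlo machinery (simulation, MDR folds and permutations, EM
  restarts) is seeded; a config seed reproduces a cohort byte for byte.

## Problem sizes used by the test suite

The suite exercises the estimators at the sizes where their guarantees are
sharp but cheap: exact-value checks on the published counts table; EM-vs-
grid-search equivalence on ≥50 panels of ≤25 individuals × 2–3 loci;
OR recovery on one 50,000-per-arm cohort (dosage fast path); Woolf CI
coverage over 500 replicates at the study's own 667-per-arm size; MDR
permutation nulls at n of a few hundred with 100–200 permutations. These
sizes are the package's own choice of where each property is informative.

## Known limitations

* No genotype imputation, phasing export, multi-allelic sites or sex
  chromosomes; PED/MAP support is read-only and strict.
* Haplotype blocks are user-declared SNP lists; there is no automatic block
  detection (Gabriel's method is out of scope).
* No exact logistic regression, permutation association P values, or
  Cochran-Armitage trend test.
* The wGRS is in-sample by default: weights estimated and evaluated on the
  same cohort overstate discrimination slightly; supply external weights
  for honest prospective evaluation.
* Published individual-level results (stratified ORs, risk-score medians,
  AUC, MDR tables) cannot be recomputed without the unpublished cohort;
  the package reproduces the counts-level tables exactly and covers the
  individual-level machinery with property-based simulation tests instead.
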