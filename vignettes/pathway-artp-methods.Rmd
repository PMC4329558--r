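---
title: "Pathway ARTP methods: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway ARTP methods: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pathARTP)
```

This vignette is the package's account of its statistical machinery: what
is computed, under which conventions, and why the open design decisions
were settled the way they were. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The analysis model

The data are a case-control cohort genotyped at SNPs that fall in or near
the genes of a candidate pathway. Three nested models are involved:

1. **Per-SNP association.** Unconditional logistic regression of disease
   status on the minor-allele dosage g ∈ {0, 1, 2} under an additive
   model, adjusting for covariates (study, sex, age stratum, genotype
   principal components):
   logit P(case) = α + β·g + γᵀz. The reported effect is the per-allele
   odds ratio exp(β) with a 95% Wald interval, and the reported p-value is
   the two-sided Wald test. The additive model is an assumption, not a
   finding: dominance or recessive effects are captured only through
   their additive component.

2. **Gene-level ARTP.** For a gene with L SNP p-values, the rank truncated
   product statistic at truncation point j is the negative log product of
   the j smallest p-values. Because the best j is not known in advance,
   the procedure scans a candidate set J and takes, per row of a shared
   permutation ensemble, the minimum of the per-truncation estimated
   p-values (MinP). The gene's adjusted p-value is the pooled share of
   ensemble rows whose MinP is at most the observed one — the
   permutation pays for the adaptive minimisation, so no further
   multiplicity correction across truncation points is needed.

3. **Pathway-level ARTP.** Stage one converts each gene's SNP columns into
   a per-row gene-level estimated p-value; stage two applies the identical
   RTP/MinP machinery across genes. Both stages are counting statistics
   over the *same* (B+1)-row ensemble; generating a second permutation
   layer would be both wasteful and wrong (it would break the coupling
   between a row's gene-level p-values).

The permutation null assumes case/control labels are exchangeable within
strata given the covariates. Labels are therefore shuffled within study,
preserving per-study case fractions; this is the exchangeability a
multi-study design actually supports. Residual confounding by covariates
that differ between cases and controls *within* a study is not removed by
the permutation — it is handled, as in the observed-data fit, by the
covariates in the score-test null model.

## Conventions that define the numbers

* **Pooled counting.** Every estimated p-value uses the pool of all B+1
  rows including the reference row itself, with ties counted (≥ on
  statistics, ≤ on MinP). Consequently every reported p-value is at least
  1/(B+1); at the default B = 20,000 the floor is 1/20001, i.e. 5.00e-05
  at three significant figures. The floor is attained exactly when the
  observed MinP is the unique strict minimum.
* **Truncation sets.** The candidate set defaults to {1, ..., min(L, 10)}
  at both levels. The cap bounds the per-row sorting work for genes with
  hundreds of SNPs while covering the qualitatively distinct signal
  shapes (one strong SNP up to ten moderate ones). Both sets are
  arguments; nothing in the machinery depends on the default.
* **Strict thresholds.** All QC filters and significance labels use
  strict inequalities (call rate < 0.90, MAF < 0.05, HWE p < 1e-4 in
  controls, completion < 0.94, gene/pathway p < 0.05, SNP report
  p < 0.001, Bonferroni p < 0.05/m). A value sitting exactly on a
  threshold is retained / not flagged.
* **Filter order.** Samples are filtered on completion first; SNP call
  rate, MAF and HWE are then computed on the retained samples only. The
  order is a documented convention (common GWAS practice); each removed
  item records the first filter it failed, so the report's counts
  reconcile step by step and `applyQc` is idempotent.
* **Coordinates and windows.** All positions are 1-based inclusive. Gene
  windows add 20 kb upstream and 10 kb downstream of the gene body,
  measured along the transcription direction: "upstream" is biologically
  directional and the asymmetric rule is meaningless otherwise. Because
  some published pipelines apply the flanks left/right regardless of
  strand, `strandAware = FALSE` reproduces that behaviour. Window ends
  are inclusive; a SNP in two overlapping windows belongs to both genes,
  contributes to both genes' ARTP, but counts once in the SNP-level
  Bonferroni family and the pathway SNP tally.
* **Minor-allele orientation.** Dosages always count the minor allele,
  determined over cases and controls combined at load time; ties at
  frequency exactly 0.5 keep their input orientation. LD r² and the score
  statistic are invariant to orientation; β merely flips sign.

## Numerical choices

* **Logistic fits** delegate to the standard IRLS (`glm.fit`, binomial
  family, convergence tolerance 1e-10, at most 25 iterations). Complete
  cases only. Degenerate inputs return status codes instead of raising:
  `monomorphic` (constant dosage), `one_class` (an outcome class absent
  from complete cases), `unstable` (non-convergence or separation,
  flagged when |β| > 15 or se > 100). The 95% interval uses
  z = 1.959964.
* **The permutation fast path** is a Rao score test: the covariate-only
  null model is fitted once per (permuted) outcome, and each SNP's
  statistic is U²/V with U = g̃ᵀ(y − μ̂), g̃ the dosage residualised
  against the covariates under the weights μ̂(1−μ̂), and V = g̃ᵀWg̃.
  Missing dosages are mean-imputed inside this path (imputed once, reused
  across permutations), whereas the observed-data Wald fit is
  complete-case — a deliberate, documented discrepancy: the score test
  only ranks rows of the ensemble, and mean imputation keeps the design
  constant across permutations. Agreement between the two routes is
  tolerance-tested (rank correlation of p-values), and with an
  intercept-only null the score statistic reduces algebraically to the
  Cochran-Armitage trend statistic.
* **HWE** uses the exact conditional test: the heterozygote count given
  the allele totals, two-sided by summing all outcomes no more probable
  than the observed one (with a 1e-9 relative guard against
  floating-point ties), evaluated in log-factorial space. The chi-square
  approximation would be unreliable exactly where the filter operates —
  near the MAF threshold.
* **PCA** standardises each SNP as (g − 2f)/√(2f(1−f)) after mean
  imputation and takes the top-k left singular vectors of the sample ×
  SNP matrix. Iterative outlier removal and LD pruning, as full
  stratification pipelines add, are out of scope; the number of PCs is a
  per-study configuration value.
* **LD** is genotype-correlation (composite) r² over pairwise-complete
  controls — deterministic and phase-free, which suffices for the
  ≥ 0.8 / < 0.2 signal groupings the reporting uses; EM-phased haplotype
  r² would be an extension. Signal grouping is single-linkage over the
  r² ≥ threshold graph, with 0.8 counting as linked.
* **Determinism.** One integer seed drives each ensemble; permutation
  order is a pure function of it, and the seed is recorded in results and
  manifests. For n ≤ 10 samples, `buildExhaustiveEnsemble` replaces
  sampling with the complete relabeling set, making every ARTP quantity
  exactly reproducible by brute-force enumeration — the package's
  strongest correctness oracle.

## The synthetic cohort generator

`simConfig`/`simulateCohort` emulate the statistical structure the
analysis assumes: multi-study case-control sampling; genotypes in exact
Hardy-Weinberg proportions (two independent haplotypes per individual) in
LD blocks generated by a first-order Markov chain with adjacent-pair
correlation ρ; uniform missingness; optional two-subpopulation
stratification (allele frequencies split by δ, plus a subpopulation
disease offset — a textbook confounder); and a retrospective case-control
outcome: a virtual population is simulated, disease probabilities follow
the additive logistic model with β = log(OR) per planted SNP, the
intercept is tuned by bisection so the expected case fraction matches the
design, and cases/controls are then sampled to exact per-study quotas.
Retrospective sampling keeps the planted odds ratios the estimands of the
logistic fit, which is what makes parameter-recovery checks meaningful.

The Markov haplotype model was chosen over multivariate-normal
thresholding because it gives HWE by construction and linear-time
sampling; its LD decays geometrically with marker distance, which is a
caricature of real haplotype structure. What the generator does *not*
emulate: realistic human LD maps and recombination hotspots, allele
frequency spectra, genotyping batch effects, imputation uncertainty, and
relatedness. Green tests therefore demonstrate correctness of the
machinery under the stated model, not robustness to everything real data
can do.

Default generator conditions: 2000 cases / 2000 controls, one study, ten
5-SNP blocks with MAF drawn from [0.1, 0.4] and ρ = 0.5, 2% missingness,
no planted effects — a deliberately modest cohort in which the null
machinery can be exercised end to end.

## Problem sizes used by the shipped checks

The test suite calibrates the permutation machinery with 500 null cohorts
of n = 400 (10 genes × 5 SNPs) at B = 200, checks parameter recovery with
200 replicates of n = 4000 at a planted OR of 1.5, sweeps every HWE
genotype triple up to 30 individuals against an enumeration oracle, and
verifies stratification correction on a 600-sample, 300-SNP confounded
null. These sizes are the package's chosen compromise between statistical
resolution (binomial bands around the nominal level) and a test suite
that runs in minutes; the statistics themselves scale to GWAS-sized
inputs, where the ensemble construction (B score scans) dominates and is
linear in B, SNPs and samples.

## Known limitations

* The ARTP adjusted p-value is granular at 1/(B+1); at B = 20,000 nothing
  below 5.00e-05 can be reported, and comparisons between values at the
  floor are uninformative.
* Score-test ranking inside the ensemble and Wald reporting outside it
  are asymptotically, not exactly, equivalent; at very small n or rare
  alleles the discrepancy grows (the exhaustive ensemble exists for
  exactly that regime).
* Complete-case per-SNP fits assume missingness unrelated to outcome
  given covariates.
* X-chromosome SNPs need sex-aware dosage conventions the package does
  not implement; the intended workflow excludes X-linked genes from the
  analysis pathway (`excludeGenes`).
* No genotype imputation, no dosage-uncertainty handling, no mixed-model
  association, no Firth correction for separation.
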