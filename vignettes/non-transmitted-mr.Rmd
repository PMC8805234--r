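---
title: "Maternal non-transmitted-allele Mendelian randomisation: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal non-transmitted-allele Mendelian randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntmr)
```

## The problem

Observational associations between a maternal exposure (the motivating case
is pre-pregnancy BMI) and offspring outcomes are confounded by everything
families share: socioeconomic environment, behaviour, and — crucially —
genes. A maternal polygenic risk score (PRS) is a tempting instrumental
variable for the exposure, but an ordinary maternal PRS fails the exclusion
restriction: half of the maternal alleles are transmitted to the child, so
the instrument is correlated with the offspring's own genotype, which can
affect the outcome directly. Adjusting for offspring genotype is not a fix:
offspring genotype is a collider between the maternal and paternal genomes,
and conditioning on it opens a biasing path whenever paternal alleles affect
the outcome.

The design implemented here sidesteps both problems by scoring only the
maternal alleles that were **not** transmitted to the offspring. Under
random mating the non-transmitted (NT) score is independent of the
offspring's genotype by construction, so no genotype adjustment is needed
and the collider never enters the model.

`ntmr` provides the full workflow: a trio simulator with known causal
structure, deterministic recovery of NT dosages from mother–offspring
genotype pairs, polygenic score construction, the estimator suite
(multivariable regression, two-stage least squares, Wald ratios), pooling,
and the diagnostics used to probe the instrumental-variable assumptions.

## The generative model

`sim_config()` / `simulate_trios()` draw, per family:

* parental haplotypes at `n_snps` biallelic SNPs, binomial in the SNP's
  effect-allele frequency (uniform in `allele_freq_range`, default
  0.05–0.95);
* Mendelian transmission: one haplotype per parent per LD block, chosen
  uniformly; the offspring genotype is the sum of the two transmitted
  haplotypes, and `mat_transmitted + mat_nontransmitted` equals the
  maternal genotype identically;
* a latent familial confounder \(C \sim N(0,1)\);
* the maternal exposure
  \(X = \sqrt{\alpha}\,\mathrm{PRS}_m + \lambda_x C + e_x\), standardised,
  so the standardised maternal score explains exactly \(\alpha\) of its
  variance;
* outcomes
  \(Y = \beta_m X + \gamma_c \mathrm{PRS}_c + \gamma_p \mathrm{PRS}_p +
  \lambda_y C + \delta' G_m + e_y\), standardised, where
  \(\mathrm{PRS}_c\) and \(\mathrm{PRS}_p\) are the offspring's and
  father's realised scores (direct genetic effects / genetic nurture) and
  \(\delta' G_m\) is optional horizontal pleiotropy acting through the
  maternal genotype.

Because every phenotype is standardised after generation, all effect
parameters are in SD-per-SD units, matching the convention in which
family-cohort analyses are reported.

The defaults (`n_trios = 5000`, `n_snps = 100`, `alpha = 0.05`,
`beta_m = 0.1`, `gamma_c = 0.2`, `lambda_x = lambda_y = 0.5`,
`rho_am = 0`) describe the reference scenario used throughout the tests: a
polygenic instrument explaining 5% of the exposure, a modest true maternal
effect, familial confounding strong enough to inflate the crude regression
by 0.25, and an offspring direct genetic effect that contaminates a
full-maternal-score instrument but not the NT score. Closed-form
path-tracing gives the large-sample values the estimators should recover:

* crude (model-one) regression slope:
  \(\beta_m + \tfrac{1}{2}\sqrt{\alpha}\,\gamma_c + \lambda_x\lambda_y\);
* MR with the full maternal score:
  \(\beta_m + \gamma_c / (2\sqrt{\alpha})\) — biased;
* MR with the NT score: \(\beta_m\) — unbiased.

These identities are frozen into the test suite as oracles.

### Assortative mating

With `rho_am > 0`, couples are rank-matched on their polygenic score plus
Gaussian noise of variance \((1-\rho)/\rho\). For standardised scores the
matched correlation is then \(1/(1+\tau^2) = \rho\) in closed form, so the
target is hit without iteration; the achieved correlation is recorded and a
shortfall beyond 0.05 is an error. Assortment induces spousal PRS
correlation in both the full and NT maternal scores, which
`parental_prs_correlation()` is designed to detect.

### Linkage disequilibrium

LD is a block copula: within a block every haplotype allele copies a block
"driver" allele with probability \(\sqrt{r}\), giving pairwise haplotype
correlation `ld_within_r` while preserving marginal frequencies. Blocks sit
on distinct chromosome labels and are transmitted whole (no recombination
within a meiosis), which keeps the transmitted/non-transmitted truth exact.
This is deliberately minimal: it exercises clumping and within-block
redundancy, but it does not reproduce realistic LD decay, allele-frequency/
LD coupling, or recombination hotspots.

### What the simulator does not emulate

Real cohort features outside the model: genotyping and imputation error,
population stratification (PCs are supported as covariates but no
structured ancestry is simulated), informative missingness (missingness is
MCAR only), measurement error in phenotypes, non-linear exposure effects,
and selection into the sample. Passing tests therefore demonstrate the
estimators' behaviour under the stated causal structure, not robustness to
those additional features.

## Duo resolution without phasing

Cohort studies phase duos with population HMMs; at package scale we use
the deterministic logic of Mendelian inheritance instead. For each
mother–child genotype pair the transmitted maternal allele is:

* forced when the mother or child is homozygous;
* resolved by a homozygous father when both mother and child are
  heterozygous;
* otherwise ambiguous: by default the expected value 0.5 is used
  (`policy = "expected"`), or the site can be dropped.

The expected-dosage policy is unbiased at symmetric sites, so scores built
from resolved dosages are classical-error-in-variables versions of the true
scores. One consequence worth stating plainly: the error variance at
ambiguous sites scales with the same sum of squared weights as the score
itself, so the correlation between resolved and true NT scores plateaus
(about 0.87 for duo-only data, 0.93 when fathers resolve half the ambiguous
sites) *regardless of how many SNPs are scored*. That correlation constant
was fixed by simulation. It is not a practical defect: classical
measurement error in an instrument attenuates instrument strength, not the
IV point estimate's consistency.

SNPs with a Mendelian-error rate above 1% (configurable) are excluded, the
standard trio-QC convention.

## Score construction

`harmonize()` aligns an external weight table to the cohort's allele
coding: exact matches kept, swapped alleles flagged for dosage flipping
(`2 - g`, preserving each SNP's contribution), strand flips resolved by
complementing, and palindromic SNPs dropped when the cohort frequency lies
in (0.4, 0.6) — outside that band they are oriented by a source
effect-allele frequency when one is supplied. `clump_and_threshold()` is
the standard greedy procedure (ascending p, id tie-break for determinism,
window in kb, squared-correlation ceiling against accepted SNPs).
`score()` computes weighted dosage sums with per-SNP mean imputation of
sporadic missingness. `standardize_within_strata()` implements the
within-stratum z-scoring convention (exposure within 1-year maternal-age
bands; outcomes within sex or sex-by-age bands), merging strata smaller
than 10 into their nearest neighbour by label order.

## Estimators and tests

* `mv_regress()` fits the three nested covariate models on one identical
  complete-case sample (rows missing *any* column used by *any* model are
  excluded), so differences between models reflect adjustment, not sample
  drift.
* `tsls()` is one-sample two-stage least squares with covariates included
  identically in both stages, homoskedastic IV standard errors by default
  (HC-robust optional), and first-stage partial \(R^2\) and
  \(F = R^2(n-k_c-k-1)/((1-R^2)k)\). F below 10 warns but never gates.
* `ratio_estimate()` is the Wald ratio with the first-order Taylor SE
  \(\sqrt{se_{ZY}^2/\beta_{ZX}^2 + \beta_{ZY}^2 se_{ZX}^2/\beta_{ZX}^4}\);
  the second-order form adds the cross term. First order is the default —
  the common usage of the Taylor approximation for pooled MR estimates.
* `meta_fixed()` is inverse-variance fixed-effects pooling with Q, df,
  p and \(I^2\); DerSimonian–Laird random effects is available as a
  sensitivity flag. `ratio_meta()` pools numerator and denominator
  coefficients separately and applies the ratio to the pooled values.
* `mv_mr_difference_test()` compares the fully adjusted multivariable
  estimate with the MR estimate using
  \(z = (\beta_{MV}-\beta_{MR}) / \sqrt{se_{MV}^2 + se_{MR}^2 -
  2\,\widehat{cov}}\), where the covariance is estimated by a paired
  nonparametric bootstrap over families (both point estimates recomputed
  per replicate; default 1000 replicates, seed recorded). The bootstrap is
  at the family level because families are the sampling units of a cohort.
* Pleiotropy diagnostics: `per_snp_wald()` + `cochran_q_snps()` for
  between-SNP heterogeneity; `mr_egger()` (weights \(1/se_{ZY}^2\),
  exposure coefficients oriented positive, plain WLS standard errors — no
  overdispersion rescaling); `instrument_validity_screen()` for
  score–risk-factor correlations with 0.05/0.001/1e-5 star bands;
  `effect_size_stratified_mr()` for the effect-size gradient; and
  `sex_interaction()` for effect modification.

### Numerical and design notes

* **Calibration regime of the difference test.** At first-stage F in the
  10–25 range the TSLS analytic SE overstates the estimator's
  finite-sample spread (the estimate shrinks toward OLS), making the
  z-test conservative. Calibration is therefore assessed — and the test is
  recommended — in the strong-instrument regime (F of order 100), which is
  where family-cohort applications of this design operate.
* **Effect-size trend scale.** The trend across weight bins is an IVW
  meta-regression of bin MR estimates on the *inverse* bin median
  absolute weight. A fixed per-SNP pleiotropic outcome effect biases a
  bin's Wald ratio in proportion to the inverse of the bin's instrument
  strength, so the bias is linear on this scale; regressing on the median
  weight itself lets the precise, unbiased large-weight bins dominate and
  reliably misses gradients that are obvious by eye. Verified by
  simulation before freezing.
* **Degenerate inputs.** Constant instruments, zero-variance strata,
  monomorphic SNPs, all-missing SNPs, a zero denominator in the ratio, and
  Mendelian-impossible genotype configurations all raise or flag
  explicitly rather than propagating NaNs. A perfect first stage returns
  an infinite-F sentinel. An all-zero weight vector yields all-zero scores
  (standardised to zero), supporting null-panel simulations.
* **Determinism.** Every stochastic routine is either governed by the
  `sim_config` seed or takes an explicit seed argument recorded in its
  output; cohorts round-trip byte-identically through the on-disk formats.

## Problem sizes used in the checks

The packaged checks run the conservation/transmission properties on 1,000
trios by 1,000 SNPs; parameter recovery on 200 simulations of 5,000 trios
by 100 SNPs; collider-bias demonstration on 60 simulations; null
calibration of the difference test on 500 simulations (2,000 trios each,
500 bootstrap replicates) with summary-level nulls (500 replicates) for
MR-Egger and Cochran's Q; power on 150 simulations of 5,000 trios; and the
clumping oracle on 100 random 20-SNP instances. These sizes give
Monte-Carlo error well inside the asserted tolerances while keeping the
whole suite in minutes on one CPU.

## Known limitations

* The duo-resolution step is deterministic and ignores population LD; a
  phasing HMM would recover some ambiguous sites and raise instrument
  strength. This is a scope decision, not an oversight: the estimator
  layer needs dosages, not phase.
* The difference test assumes the bootstrap covariance is estimated on the
  same estimand pair as the analytic SEs; with very weak instruments its
  null behaviour is conservative (see above).
* MR-Egger here is the summary-level regression; no SIMEX or
  overdispersion variants.
* The simulator's LD and assortment models are intentionally stylised;
  conclusions about fine-scale LD behaviour (e.g. clumping window choice
  on real data) should not be drawn from it.
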