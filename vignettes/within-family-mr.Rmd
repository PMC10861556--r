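---
title: "Within-family Mendelian randomization: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-family Mendelian randomization: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duomr)
```

## The estimation problem

A mother's polygenic score (PGS) for maternal effects on offspring birth
weight can serve as an instrument for intrauterine growth in a Mendelian
randomization (MR) analysis of the child's later-life disease risk. The
exclusion restriction, however, is threatened by transmission: the child
inherits one allele per locus from the mother, so mother and child PGSs
correlate at 0.5 under random mating, and any pleiotropic action of the
same variants in the child's own genome opens a back-door path from the
mother's score to the child's outcome.

`duomr` fits the three logistic models that diagnose this situation on
identical rows of duo-level data — parent score only, child score only, and
both jointly — reporting each effect as a log odds ratio per SD of PGS with
Wald standard errors. Conditioning on the child's score blocks the
transmission path. Asymptotically, with standardized scores of correlation
$\rho$ and small effects:

* pure fetal effect $\beta_C$: the parent-only slope converges to
  $\rho\,\beta_C$ and the joint parent slope to 0;
* pure maternal effect $\beta_M$: the parent slope is the same (up to
  sampling noise) with or without adjustment, because the child's score is
  conditionally independent of the outcome given the mother's.

These two laws are verified by simulation at $10^6$ pairs in the test
suite, and the attenuation ratio (joint / unadjusted parent logOR) is the
packaged diagnostic. The same estimator applied to father–child duos is a
negative control (no intrauterine path), and conditional logistic
regression on disease-discordant same-sex full-sibling pairs isolates the
child-genome effect exactly, since siblings share the maternal genotype:
for 1:1 matched pairs the conditional likelihood per pair is
$e^{\beta x_{case}} / (e^{\beta x_{case}} + e^{\beta x_{control}})$,
which depends only on the within-pair score difference.

## What the simulator emulates

The synthetic cohort generator reproduces the statistical structure the
analysis relies on, and nothing more:

* **Genotypes.** Parental dosages are Binomial(2, eaf) per locus
  (Hardy–Weinberg, random mating); each child allele is drawn uniformly
  from the corresponding parent's two alleles, independently across loci.
  This yields the parent–child and sibling score correlations of 0.5 that
  drive the whole design. Loci are independent — no linkage
  disequilibrium — and autosomal; an optional Gaussian-copula re-pairing of
  spouses emulates assortative mating when requested (default off).
* **Panel.** Variant classes follow the maternal/fetal partition of
  lead-SNP birth-weight panels; the default class mix 32:68:27:15:71
  (maternal-specific : fetal-specific : shared-concordant :
  shared-opposing : unclassified) mirrors the composition of such panels.
  Weights are half-normal within class, oriented so the effect allele
  increases birth weight through its defining genome, with opposing-class
  fetal weights negative.
* **Birth weight.** `assign_birthweight()` standardizes the weighted
  maternal-genome and fetal-genome components empirically and mixes them to
  explain `h2_maternal` and `h2_fetal` of the phenotypic variance, then
  rescales to a mean of 3500 g and SD of 500 g — typical Northern-European
  values. Lead-SNP scores explain little birth-weight variance in practice
  (a 1 SD change in a maternal-specific score corresponds to a few tens of
  grams), hence the modest defaults `h2_maternal = 0.02`,
  `h2_fetal = 0.05`.
* **Disease.** Case status is Bernoulli from
  $\mathrm{risk} = \mathrm{plogis}(\alpha + \beta_C\,PGS_{child} +
  \beta_M\,PGS_{mother})$. Scenarios are parameterised by odds ratios per
  SD and a target prevalence; the `via_birthweight` mediation variant
  routes the maternal effect through the generated birth weight instead,
  emulating a true intrauterine mechanism.
* **Covariates.** Children's ages are normal (mean 46.3, SD 14.2 years,
  truncated at 18), matching the age structure of adult biobank offspring;
  principal-component surrogates are pure noise and the genotyping batch is
  random, because the generator produces no population structure or batch
  effects — they exist so model plumbing (covariate handling, rank checks)
  is exercised, not to inject confounding.

Passing tests on these cohorts therefore demonstrate the *estimators'*
properties (identification, calibration, power), not robustness to LD,
stratification, genotyping error, non-random mating or real-world
ascertainment, none of which are generated.

## Numerical choices

* **Intercept calibration.** $\alpha$ solves
  $E[\mathrm{plogis}(\alpha + sZ)] = \text{prevalence}$ with
  $s^2 = \beta_M^2 + \beta_C^2 + 2\rho\beta_M\beta_C$, integrating over
  $Z \sim N(0,1)$ by 60-node Gauss–Hermite quadrature and root-finding with
  `uniroot` (tolerance 1e-12). This is deterministic and seed-independent;
  the realized case fraction then matches the target up to binomial noise.
  For `via_birthweight` scenarios the linear predictor has no closed-form
  law after empirical standardization, so $\alpha$ is root-found on the
  realized predictor instead.
* **Logistic fitter.** An in-package Newton/IRLS engine converges on a
  score-norm tolerance of 1e-8, errors explicitly on rank deficiency
  (naming the collinear columns) and on diverging coefficients
  (|logOR| > 15, complete or quasi-complete separation), and offers Firth's
  Jeffreys-prior penalty as an opt-in for small strata. Silent penalization
  is avoided because it changes the estimand. The fitter is cross-checked
  in the tests against `stats::glm` and an independent brute-force Newton
  reference to 1e-6.
* **Conditional logistic regression** uses `survival::coxph` with the
  exact partial likelihood (the `clogit` construction). Tied pairs
  contribute likelihood 1/2 for every $\beta$ and are retained; an
  all-tied pair set is an explicit unidentifiability error, and one-sided
  informative pairs raise a separation error.
* **Seeds.** Every stochastic stage takes one user seed; internal stages
  and replicates derive child seeds by a counter scheme (kept below
  $2^{31}$), so per-replicate results are reproducible and independent of
  evaluation order or parallel schedule.

## Power analysis

`simulate_once()` executes the four-step replicate — bivariate-normal PGS
pairs (means 0, variances 1, correlation 0.5), calibrated logistic risk,
Bernoulli outcomes, joint fit — and `estimate_power()` aggregates the
fraction of Wald p-values below $\alpha$ over `reps` replicates (default
1000) with its binomial Monte-Carlo SE. `min_detectable_or()` searches the
OR grid $1 + k \cdot 0.01$ by bisection, which is valid because power is
monotone in the true OR; the reported boundary carries the MC uncertainty
of its bracketing grid points, so at 500–1000 replicates the boundary is
reliable to about one grid step. A draw with zero cases is an error by
default (at biobank prevalences it essentially never occurs); opt-in
resampling exists for exploratory small-n use but would bias power there,
which is why it is not the default.

At the study scale this package targets — 36,211 duos, case counts from
996 to 6,150 — the joint model reaches 80% power for maternal odds ratios
of roughly 1.11 and 1.05 per SD at the two bracketing prevalences;
`scripts/acceptance.R` recomputes these boundaries.

## Design choices where the design was open

* **Standardization reference** for PGSs defaults to the pooled cohort
  (all roles together); within-role standardization is available by flag.
  The pooled choice keeps one SD unit shared by mother and child terms, so
  their coefficients are directly comparable.
* **Missing data.** Panel variants absent from the genotype data are
  dropped with a reported count and no re-weighting of the remainder
  (scoring then uses, say, 29 of 32 variants); missing genotypes within a
  retained variant are mean-imputed from the cohort so case-wise deletion
  cannot silently change the sample size.
* **Multiplicity of sibling pairs.** When a family offers several
  same-sex discordant duos, one is chosen uniformly at random under the
  stage seed; keeping all of them would correlate pairs within a family.
* **Independent-pair filters.** `one_child_per_mother` keeps the oldest
  child per mother deterministically; `max_4th_degree` keeps the oldest
  parent's oldest child per family, which in simulated cohorts (unrelated
  across families) is exactly the closer-than-4th-degree pruning.
* **Attenuation uncertainty.** The attenuation ratio is a ratio of
  estimates from nested models with no standard closed-form SE; a
  pair-resampling bootstrap CI is available via `boot_reps`. It is off by
  default because refitting three models hundreds of times at biobank
  sample sizes is expensive relative to its diagnostic value; enable it
  when the ratio itself is a reported quantity.
* **Significance** is two-sided p < 0.05 throughout, with no
  multiple-testing correction — the endpoints of interest overlap and the
  scores are nested, so a family-wise correction would be miscalibrated.
* **No formal IVW/Egger estimators.** The package tests the *presence* of
  maternal effects under the within-family design; it does not estimate
  causal effects on the birth-weight scale, and monotonic risk is assumed
  (no J-shaped birth-weight–risk models).

## Problem sizes used in the shipped checks

The test suite exercises transmission and score laws at 4,000–15,000
families with 60–100 variants, the model-identification laws at $10^6$
simulated duos, coverage and type-I error at the full 36,211-duo scale
with 1,000 replicates, and the power boundaries at 500 replicates per
0.01-grid point. These sizes make every Monte-Carlo tolerance (3 SE, or
the stated absolute bounds) sharp enough to detect real defects while
keeping a full run on one CPU in the tens of minutes.

## Known limitations

Beyond the simulator's idealizations listed above: hard-call genotypes are
simulated (fractional imputed dosages are accepted on input but not
generated); sibships larger than two are not matched as larger sets;
X-chromosome transmission and parent-of-origin (imprinting) effects are
out of scope; and the power analysis does not model how much birth-weight
variance a PGS explains, so its odds-ratio boundaries translate to
clinical effect sizes only indirectly.
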