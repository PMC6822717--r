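---
title: "Stratified MR phenome scans: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified MR phenome scans: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxescan)
```

## The method

Mendelian randomization (MR) uses a genetic variant as an instrument for a
modifiable exposure. A phenome scan (MR-pheWAS) tests that instrument
against thousands of automatically-typed outcomes at once; its weakness is
horizontal pleiotropy — the variant affecting outcomes through pathways
other than the exposure. The gene-by-environment (GxE) variant of the design
addresses this by stratifying the sample on a phenotype across which the
exposure manifests differently (the canonical case: ever vs never smokers,
with smoking heaviness as the exposure and a heaviness-associated variant as
the instrument). If the variant acts on an outcome through the exposure, its
per-allele association with the outcome should be present in ever smokers
and absent (or attenuated) in never smokers; a pleiotropic pathway shows up
equally in both strata.

`gxescan` implements the full pipeline:

1. **Typing** (`derive_outcomes()`): raw biobank fields (integer,
   continuous, categorical-single, categorical-multiple) are converted by
   deterministic rules into outcomes of four data types — continuous,
   binary, ordered, unordered. Categorical-multiple fields expand into one
   binary outcome per recorded value with absence coded 0 (no missingness).
   Continuous outcomes are inverse-normal rank transformed. Typing runs once
   on the full sample so every stratum sees identical data types.
2. **Stratified scan** (`run_phenome_scan()`): per stratum, each testable
   outcome is regressed on the instrument dosage (numeric 0/1/2, additive
   coding) with covariate adjustment — linear, logistic, proportional-odds
   or multinomial regression by data type. An outcome is testable in a
   stratum with at least 500 non-missing participants and (binary/unordered)
   at least 10 per category.
3. **Ranking** (`interaction_ranking()`, `fdr_select()`,
   `two_step_interaction()`): outcomes tested in both strata under the same
   model are ranked by the P value of Cochran's fixed-effect Q between the
   stratum estimates (log-odds scale for categorical models — multiplicative
   interactions). Multiple testing uses a Bonferroni threshold
   `alpha / n` and the step-up FDR rule: the largest rank k with
   `P(k) < alpha * k / n`. A two-step variant first selects whole-sample FDR
   hits, then ranks only those by interaction strength at the reduced n.
4. **Bias studies** (`run_bias_grid()`, `run_fdr_inflation_sim()`): because
   the instrument is (weakly) associated with the stratifying phenotype,
   stratifying conditions on a collider whenever a confounder affects both
   the stratum and an outcome. The simulations quantify the resulting
   per-stratum bias and the inflation of the phenome-wide false discovery
   rate.
5. **IV follow-up** (`build_allele_score()`, `instrument_strength()`,
   `iv_probit()`, `ordered_logistic_followup()`): unweighted allele-score
   instruments, first-stage strength with percentile case-bootstrap
   confidence intervals, and a two-stage IV probit whose coefficient b is
   reported on the odds scale as `exp(1.6 * b)`.

## Key assumptions

* Instrument relevance within the exposed stratum, and — for the GxE logic —
  no association between instrument and the stratifying phenotype strong
  enough to induce material collider bias (the bias simulations make this
  quantitative).
* Interactions are assessed on the scale of the fitted model (SD units for
  transformed continuous outcomes, log odds otherwise); Q's chi-square
  reference assumes approximately normal per-stratum estimates.
* Complete-case analysis per outcome; covariates in a stratum are assumed
  missing rarely enough that complete cases are representative.
* The proportional-odds model is used without a proportionality test;
  multinomial outcomes get a whole-model likelihood-ratio P and no scalar
  estimate, so they are excluded from interaction ranking (they remain in
  main-effect rankings).

## Tunable parameters

| Parameter | Default | Rationale |
|---|---|---|
| `max_ordered_levels` | 20 | integer/continuous fields with at most this many distinct values become ordered categorical ("a few distinct values"); configurable because published rule trees differ |
| transform offset | `(r - 0.5)/m` | midpoint rank offset; Blom's `(r - 3/8)/(m + 1/4)` available |
| tie policy | random permutation | average ranks would create point masses and defeat normalization; the permutation seed is an argument and is logged |
| `min_n`, `min_per_category` | 500, 10 | stratum testability filters (boundaries inclusive) |
| `alpha` | 0.05 | FDR level and Bonferroni family-wise rate |
| step-up inequality | strict `<` | `P(k) < alpha*k/n` exactly as specified in the procedure this package implements; conventional Benjamini–Hochberg uses `<=`, which differs only when a P value ties the threshold |
| covariates | age, sex, 10 PCs | standard biobank adjustment; a 40-PC sensitivity set is a covariate configuration, not a different method |
| `exp(1.6 b)` | fixed 1.6 | logit/probit scale factor used for the odds-scale conversion of probit coefficients |
| bootstrap | percentile, case resampling, 1000 draws | valid under heteroscedastic, non-normal residuals; percentile (not BCa) for determinism and simplicity |

## The synthetic biobank

Restricted cohort data cannot ship with a package, so every stage is
validated against `simulate_biobank()`, whose defaults are the study
conditions themselves: 334,968 participants; ever-smoking prevalence 0.452
(182,961 never / 150,831 ever); an instrument SNP in Hardy–Weinberg
equilibrium with effect-allele frequency 0.33 (the frequency is not reported
in the source analysis; 0.33 matches European-ancestry estimates for the
canonical heaviness variant); per-allele odds 0.98 on ever-smoking and 1.21
on being in a higher cigarettes-per-day band (0–10, 11–20, 21–30, 31+,
default marginal proportions 0.33/0.45/0.14/0.08 — a configured stand-in for
UK smoking patterns). Smoking status comes from a logistic model whose
intercept is calibrated by bisection to the marginal prevalence (tolerance
1e-6 — marginal prevalences are what is reported, not intercepts); heaviness
from a proportional-odds latent-logistic model cut at the configured band
proportions; ordinal outcomes generally from latent variables cut at fixed
thresholds. Covariates are age ~ U(40, 69), sex ~ Bernoulli(0.5), and
principal components that are standard normal and independent of genotype
(population structure itself is out of scope). Missingness is completely at
random.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: linkage disequilibrium, imputation uncertainty,
relatedness and dynastic effects, selective participation, informative
missingness, reporting bias of the stratifying phenotype, and real
phenotype-phenotype correlation structure. Parameter-recovery results on
synthetic data show the machinery is correct, not that a real phenome meets
the assumptions.

For simulation studies that need thousands of outcomes,
`simulate_outcome_matrix()` and `run_matrix_scan()` operate on plain
matrices through the same shared-design least-squares engine the phenome
scan uses for fully-observed continuous outcomes (the equality is tested to
1e-10 against `lm()`). The calibration and recovery studies in the test
suite use these at the study's own sizes: 1,000 null outcomes at 20,000 per
stratum over 200 replicate scans (calibration), and a 0.1 SD/allele
ever-only effect against 1,000 nulls at 50,000 per stratum over 100
replicates (recovery and ranking). Those outcomes are generated directly on
the N(0,1) scale, where the inverse-normal transform is a near-identity; the
transform itself is exercised end-to-end in the typing and pipeline tests.

## The collider simulations

A standard-normal confounder U affects ever-smoking (odds ratio
`or_conf_status` per SD, additive with the SNP on the log-odds scale — no
product term, matching the benign-case description; an interaction term can
be added for exploration) and each outcome
(`Y = s * sqrt(r2) * U + beta * G + sqrt(1 - r2) * e`, unit marginal
variance under the null `beta = 0`). The ordinal "facial-aging" outcome cuts
Y at standard-normal quantiles of configurable marginal proportions (default
0.55/0.40/0.05 — a free parameter; no split is reported). The scan inside
the simulations regresses outcome on dosage without covariates: the
generative process contains no covariate signal, so adjustment would only
spend time.

`run_fdr_inflation_sim()` reports two summaries over replicate scans of an
all-null phenome:

* **`fdr`** — the empirical false discovery rate in its standard form, the
  replicate mean of V/R (declared-false over declared, 0 when nothing is
  declared). With every outcome null, V/R is 1 exactly when a scan declares
  at least one hit, so this equals the fraction of replicate scans making
  at least one false discovery. This is the quantity on which the shared
  confounder acts: it correlates all tests within a scan, so occasional
  scans cross the step-up threshold together.
* **`prop_flagged`** — the mean fraction of outcomes declared (a
  false-positive proportion). Because the per-test bias induced by a
  plausible instrument-stratum association is a fraction of one standard
  error, this stays near zero even where `fdr` is visibly inflated; the two
  numbers answer different questions and both are returned.

One structural property of this generative model is worth recording: the
collider-induced per-test bias is proportional to the instrument's log odds
on the stratum divided by the confounder's, times a bounded derivative of
the selection function — so as the confounder's odds ratio grows very large
(stratum membership becoming a near-deterministic function of U), the bias
*shrinks* again after peaking at moderate strength. Inflation is therefore
monotone in the confounder-outcome strength r² at fixed odds ratio, but not
strictly monotone in the odds ratio at fixed r² across the top of the
10–100 grid. The acceptance checks compare collider-present against
collider-absent cells and verify the simulation-wide ceiling rather than
asserting strict odds-ratio monotonicity.

Simulation sizes: the headline cell (odds ratio 100, r² = 0.2, 1,000
outcomes, full biobank scale) runs 40 replicates in the test suite and 100
in the acceptance script; Monte-Carlo standard errors accompany every
summary, and comparisons use 3 MC SE bands with the binomial SE at the
target rate as a floor (so an unlucky all-zero replicate set cannot
masquerade as precision).

## Numerical choices

* Continuous-outcome scans solve the shared design by Cholesky-factored
  normal equations with a QR fallback that names collinear columns;
  identical (to 1e-10) to `lm()` on well-conditioned designs.
* Logistic/probit fits use `stats::glm`, proportional odds `MASS::polr`
  (maximum likelihood with analytic gradients), multinomial
  `nnet::multinom`; all are cross-checked in the tests against hand-written
  likelihood maximizers on small data. Non-convergent or separated fits are
  flagged, excluded from ranking, and logged with the exclusions.
* Wald P values for scalar estimates (the Q statistic needs an
  estimate/SE pair on a common scale); likelihood-ratio P only for the
  multinomial model. Whether the original ordered-logistic P was Wald or LR
  is not documented; Wald is used and stated.
* Bulk normal deviates come from a xoshiro256++/ziggurat generator in C++
  (~4x R's `rnorm` throughput here), validated against the normal
  distribution by Kolmogorov–Smirnov at n = 1e6, moment checks, and tail
  frequency ratios at |z| > 3 and 4. All simulation entry points accept a
  seed; a fixed seed reproduces results bit-for-bit, and the C++ stream is
  seeded from the R stream so `set.seed()` governs everything.
* Degenerate inputs: constant outcomes are dropped with a logged reason
  (the transform is undefined up to ties); a multi-level categorical-single
  field without declared ordering is a configuration error rather than a
  guess; `fdr_select()` with k = 0 reports an explicitly not-applicable
  threshold.

## Known limitations

* Two strata are the tested configuration; the Q machinery accepts k > 2
  but the scan orchestration is ever/never/full.
* No robust or clustered standard errors, no relatedness modelling, no
  exact logistic regression for rare outcomes (the 10-per-category filter
  is the guard).
* The empirical-FDR headline depends on unpublished details of the original
  simulation (the number of outcomes per scan and of replicates); the
  acceptance script computes it at 1,000 outcomes and 100 replicates, and
  comparisons at other sizes carry Monte-Carlo tolerance.
* Estimating the magnitude of exposure effects (rather than detecting their
  presence) is out of scope except for the IV follow-up of a single
  outcome.
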