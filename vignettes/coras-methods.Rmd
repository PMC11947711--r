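---
title: "CoRAS: scoring model, synthetic cohorts, and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CoRAS: scoring model, synthetic cohorts, and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coras)
```

## The scoring model

CoRAS sums eight integer point contributions — consciousness (Japan Coma
Scale), SpO₂, suctioning frequency, sitting balance (Hoffer), swallowing
(FILS), respiratory disease history, nutrition (MUST/GLIM) and saliva
(OHAT-J) — into a 0–100 composite. The weights were fixed by
multidisciplinary consensus, not estimated; this package treats them as
constants and deliberately provides no re-weighting. All scoring arithmetic
is integer: there is no floating point anywhere between a raw assessment and
the composite total, so scores are exactly reproducible across platforms.

Two details of the printed scoring criteria required a decision:

* **FILS band overlap.** The published bands "level 8–10 → 0" and "level
  7–9 → 5" overlap at levels 8–9. We resolve the overlap in favour of the
  less severe band, giving the partition 8–10 → 0, 7 → 5, 4–6 → 10,
  1–3 → 15. This keeps every FILS level mapped to exactly one point value
  and preserves the scale's severity ordering (lower level, more points). It
  is a documented interpretation, not a stated intent of the score's
  authors.
* **Sub-daily suctioning.** Patients suctioned more than never but less
  than once daily are not addressed by the printed bands; the package's
  schema carries band codes, and such a patient should be coded into the
  "1–7 times/day" band.

The respiratory-disease input is a raw diagnosis count, banded internally
(0 / 1 / 2 / ≥3), and SpO₂ accepts an `on_oxygen` flag that forces the worst
band regardless of the numeric reading, since oxygen therapy and ≤91% share
one band. Risk categories are a pure threshold function of the total:
0–14 low, 15–39 moderate, 40–100 high, boundaries inclusive.

Exhaustive enumeration of all 4·3·3·3·4·4·3·3 = 15,552 band combinations
(`enumerate_scores()`) confirms the attainable totals span exactly 0–100,
and worsening any single parameter while holding the rest fixed never
decreases the total; both properties are asserted in the test suite.

## The synthetic cohort generator

No patient-level data accompany the score, so the validation pipeline is
exercised on synthetic cohorts whose structure matches the published
aggregate description of the 629-patient development cohort:

* **Marginals.** Per-parameter band frequencies default to the published
  univariate counts (e.g. consciousness 295/276/52/6 of 629). The printed
  saliva column sums to 512 rather than 629 — an internal inconsistency of
  the source tables — so its counts (17/430/65) are used as relative
  frequencies.
* **Dependence.** The eight published pairwise correlations are interpreted
  as the correlation matrix of a latent multivariate normal, and ordinal
  bands are produced by cutting each latent coordinate at the
  standard-normal quantiles of its marginal (a Gaussian copula). The source
  does not state whether its correlations are Pearson or rank correlations
  of the point scores; the latent-Gaussian reading is an implementation
  choice. Realized rank correlations of the ordinal scores are attenuated
  relative to the latent targets (e.g. latent 0.65 between sitting balance
  and swallowing realizes near 0.54 at n = 50,000), so exact recovery of the
  published matrix is not a contract — but the *ordering* of strong versus
  weak pairs is preserved and tested. Published values need not form a
  positive-definite matrix in general; `repair_correlation()` clips
  eigenvalues at a floor of 1e-6 and re-normalizes the diagonal. The default
  matrix happens to be positive definite already (smallest eigenvalue
  ≈ 0.26) and passes through unchanged.
* **Covariates.** P(male) = 337/629 and P(care certified) = 172/629. Age is
  a normal distribution truncated to [18, 105] years with mean 74 and SD
  13.3, moment-matched to the published median 74 and IQR 64–82; the
  asymmetry of the printed IQR (−10/+8) cannot be captured by a symmetric
  model, and only median/IQR are available to fit anything richer.
* **Outcome.** Pneumonia is Bernoulli with
  `logit p = β₀ + log(1.06)·total + log(2.19)·care + log(1.73)·male +
  log(1.00)·(age − mean age)`, the published adjusted odds ratios. Age is
  centered at the sample mean so the intercept calibration is stable. The
  intercept β₀ is solved by bisection so the *mean model probability* over
  the sampled cohort equals the 7.6% target prevalence, to 1e-6 on the
  probability scale; the realized event count then varies binomially around
  the target.
* **Raw values below band resolution.** A FILS level is drawn uniformly
  within its scored band; a diagnosis count in the "≥3" band is fixed at 3.
  Finer structure is unobservable in the published tables.
* **Determinism.** One seed feeds a single pseudo-random stream with a fixed
  draw order (latent bands, FILS level, age, sex, care, outcome), so a
  config plus seed reproduces a cohort byte for byte, and the sidecar JSON
  written next to a generated CSV (seed, realized intercept, config hash)
  suffices to regenerate it.

**What passing tests on synthetic cohorts show — and what they do not.** The
generator reproduces marginals, a monotone dependence structure, covariate
mixes, and a log-linear score–outcome effect. It does not model real-data
features such as assessment error, within-ward clustering, informative
missingness (the development cohort reported none), non-linear score
effects, or outcome timing. Recovery of the per-point odds ratio on
synthetic data therefore validates the *pipeline* — that the estimator finds
the effect that is there — not the clinical performance of the score, and
the published patient-level headline numbers (AUC 0.85/0.86, max VIF 2.11,
the exact correlation range) are reproduced only as qualitative patterns:
score-containing models dominate the covariates-only model, VIFs stay well
below 5, and the strong correlation pairs stay strong.

## Validation statistics

Every statistic of the four published analyses is implemented directly in
the package, with established implementations (`chisq.test`, `wilcox.test`,
`glm`, `car::vif`, `pROC`) used as independent cross-checks in the test
suite rather than as the implementation:

* **Contingency tests.** Pearson chi-square with `df = (r−1)(c−1)`; 2×2
  tables get the Yates continuity correction by default (the conventional
  default in the clinical statistical environments these analyses are run
  in), exposed as a flag; larger tables are never corrected.
* **Mann-Whitney U** with midrank ties and the tie-corrected normal
  approximation, U reported for the first group (pairwise wins plus
  half-ties; verified against an O(n²) oracle).
* **Correlation matrix.** Midrank (Spearman) correlation by default —
  appropriate for ordinal point scores — with a product-moment option, since
  the source does not state which was used. Constant columns yield `NA`
  entries, never a silent zero.
* **VIF.** `1/(1−R²)` from the least-squares regression of each predictor on
  the others plus an intercept. VIF is a property of the predictor columns
  alone; the source's phrasing ties its VIF computation to the outcome
  variable, which standard VIF does not use, and the package implements the
  standard definition. Exact collinearity yields an infinite VIF with the
  offending predictors named, not an exception. Acceptability is flagged at
  the stated cutoff of 5.
* **Logistic regression** by iteratively reweighted least squares:
  convergence at max |Δβ| < 1e-8 within 50 iterations, standard errors from
  the inverse Fisher information, 95% Wald intervals `exp(β ± 1.959964·SE)`
  (matching the symmetric-on-the-log-scale intervals of the published
  table; profile likelihood is deliberately not offered), and
  `AIC = −2·loglik + 2·(coefficients incl. intercept)`. Separation is
  detected (fitted log-odds diverging beyond ±25) and flagged as a
  non-converged fit with diagnostics rather than an error. The one-binary-
  predictor fit reproduces the 2×2 closed form OR = ad/bc and
  SE = √(1/a+1/b+1/c+1/d) to ten significant digits in tests.
* **ROC/AUC.** Thresholds at every unique score value; the trapezoidal AUC
  equals the tie-adjusted concordance statistic exactly (asserted on every
  fixture), with DeLong structural-component variance for the 95% CI and the
  paired z-test for correlated AUC differences.
* **Model comparison.** Both readings of "the models were compared by
  chi-square tests" are computed side by side: the likelihood-ratio
  chi-square for nested fits and the paired DeLong AUC test. The
  covariates-only and score-only models are not nested in each other, so
  only the AUC branch applies there; both are nested in the full model.
* **Screening metrics.** The published convention is unusual: condition
  positive is the *absence* of pneumonia and a positive screen is the
  low-risk category, so sensitivity = P(low | no pneumonia) and
  specificity = P(not low | pneumonia). The package reports this convention
  and the conventional orientation side by side, each labeled, to prevent
  misreading.
* **P-values** render as three decimals with "<0.001" collapsing, matching
  the published table style. No multiple-testing correction is applied, as
  none was applied in the source analyses.

## Numerical and simulation design choices

* Intercept calibration: bisection on [−50, 50], tolerance 1e-6 on the mean
  probability; a non-bracketing target raises a diagnostic error.
* IRLS weights are floored at 1e-12 to keep the weighted least-squares step
  well-posed near saturated probabilities.
* The null-calibration simulation (type-I error of the LRT at α = 0.05 over
  1,000 replicates) uses per-replicate cohorts of n = 400 with an event
  fraction near 0.27 (~110 events). At substantially smaller replicate
  sizes the LRT's small-sample inflation (measured ~0.07 at n = 150,
  replicate-for-replicate identical to `glm`/`anova`) dominates the Monte
  Carlo tolerance; n = 400 keeps the chi-square asymptotics that the 5%
  claim assumes in their validity range while the 2,000 model fits complete
  in seconds.
* Parameter-recovery and prevalence-calibration checks use n = 20,000
  cohorts (roughly 1,500 events), where the per-point odds ratio's Monte
  Carlo standard error (~0.004 on the OR scale) is comfortably inside a
  two-decimal check; marginal-fidelity checks use n = 50,000 draws against
  three binomial standard errors.

## Replaying published aggregate tables

`replay_risk_table()` accepts a pre-tabulated risk-category × outcome table,
so published counts are directly replayable:

```{r}
replay_risk_table(matrix(c(283, 222, 76, 2, 13, 33), nrow = 3))
```

This reproduces the 7.6% overall prevalence, the 0.7% low-risk incidence,
and the 0.49/0.96 screening pair. Note the published narrative incidences
for the moderate (5.9%) and high (43.4%) categories are inconsistent with
the published counts themselves (13/235 ≈ 5.5%, 33/109 ≈ 30.3%); the package
computes from counts and leaves the discrepancy documented rather than
resolved.

## Known limitations

* The latent-Gaussian reading of the published correlations, the symmetric
  age model, and the uniform within-band FILS draw are all simplifications
  forced by aggregate-only reporting; none is testable against patient data.
* The generator models an admission snapshot and a binary outcome only — no
  length of stay, pneumonia timing, or score trajectories.
* The consensus weighting process behind the point values is out of scope;
  the package will not re-derive or re-weight the score, and no alternative
  risk thresholds are offered.
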