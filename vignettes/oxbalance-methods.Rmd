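---
title: "Methods: oxidative balance scoring and design-based risk analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oxidative balance scoring and design-based risk analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxbalance)
```

This vignette documents the models the package implements, the conventions
and tunable parameters behind them, what the synthetic cohort emulates, and
the design decisions taken where the methodology was genuinely open.

## The oxidative balance score

The OBS sums 0–2 points over 20 components (16 dietary, 4 lifestyle; 5
pro-oxidants, 15 antioxidants). The default component table
(`obs_components()`) assigns the dietary antioxidants {fiber, total
carotene, riboflavin, niacin, vitamin B6, total folate, vitamin B12,
vitamins C and E, calcium, magnesium, zinc, copper, selenium}, dietary
pro-oxidants {total fat, iron}, the lifestyle antioxidant {physical
activity, MET-min/week} and lifestyle pro-oxidants {BMI, serum cotinine,
alcohol}. Epidemiological OBS variants differ in exactly which nutrients
enter; the table is therefore data, not code — `read_components()` accepts
an edited CSV, and validation only enforces the structural counts (20 =
16 + 4, 5 pro-oxidants, one alcohol-rule component). Two choices were open
and are defaults rather than facts: *total* carotene represents the
carotene family (alpha/beta-carotene can be substituted via the table), and
physical activity is tertile-scored like the nutrients rather than scored
from activity categories.

**Tertile convention.** Cutpoints are the 1/3 and 2/3 empirical quantiles,
inverse-ECDF (`type = 1`), computed *unweighted* within each sex stratum on
the analytic sample; scoring intervals are right-closed (`value <= t1` is
the bottom tertile). Inverse-ECDF quantiles make the cutpoints order
statistics, so a brute-force sort-and-split oracle reproduces them
bit-for-bit — that exactness is why the convention was fixed this way.
Survey-weighted tertiles are a defensible alternative; unweighted is the
common practice for published OBS constructions and is what the tests pin
down.

**Alcohol.** Abstainer (exactly 0 g/day on the recall) scores 2, non-heavy
1, heavy 0, with heavy defined as intake at or above 15 g/day for women and
30 g/day for men. Treating the threshold itself as heavy makes the three
categories exhaustive and mutually exclusive; "abstainer = exactly zero" is
the only operational reading when only recall intake is available.

**Missingness.** A row missing any component gets `NA` scores; exclusion is
complete-case and happens in the pipeline's exclusion cascade. Nothing is
imputed inside the scoring module.

**Quartiles.** Score quartiles use the same inverse-ECDF/right-closed
convention (ties at a boundary fall into the lower quartile), so group
sizes deviate from n/4 only by tie mass at the boundaries.

## Pooled Cohort Equations

Ten-year first-ASCVD-event risk is `1 − S₁₀^exp(LP − mean LP)` with
group-specific coefficients for the four sex × race groups. Coefficients
live in `inst/extdata/pce_coefficients.csv` with a provenance column and a
checksum logged at load time, so the transcription from the source
guideline is auditable and replaceable; they are never hard-coded in the
analysis path (the test suite carries an independent hand transcription as
its oracle). NHANES race categories map black → African-American equations
and white/other → white equations, the guideline's stated practice for
groups without dedicated equations. Ages outside the PCE-valid range
[20, 79] are flagged and excluded by the pipeline, never clamped —
clamping would silently distort risk at the boundaries. The high-risk
threshold is right-closed: predicted risk exactly 7.5% is high.

## Design-based inference

NHANES-style samples are stratified multi-stage cluster samples with
examination (MEC) weights. All regressions here are weighted and the
variance is design-based:

- **Point estimates** solve the weight-multiplied score equations
  (logistic: IRLS with weights; Cox: weighted partial likelihood with
  Breslow tie handling). Weights are normalized to mean one internally —
  estimates and the linearized variance are invariant to the weight scale,
  and population-scale weights (tens of thousands) otherwise degrade IRLS
  conditioning.
- **Variance** by Taylor linearization: per-row influence contributions
  (inverse information times score residuals for the logistic model;
  weighted dfbeta residuals for Cox) are summed to PSU totals, and the
  between-PSU covariance of those totals accumulates within strata with
  the n_h/(n_h − 1) factor. With one stratum, singleton PSUs and equal
  weights this collapses to the heteroskedasticity-robust sandwich, which
  the tests verify against independent implementations.
- **Lonely PSUs** (a stratum with a single sampled PSU) cannot contribute
  a within-stratum variance; their total is centered at the grand PSU mean
  and a warning is raised. This is conservative; dropping such strata
  would underestimate the variance silently.
- Confidence intervals are normal-approximation on the log-odds/log-hazard
  scale, 95% everywhere; p-values two-sided at 0.05.

Combined survey cycles should use the standard weight adjustment (cycle
weight divided by the number of cycles) before calling the fitters; the
fitters themselves are agnostic to how the weight column was built.

Separation in the logistic model (boundary fitted probabilities or a
vanishing deviance alongside diverging coefficients) raises an explicit
error rather than returning meaningless estimates, as does non-convergence.

## Restricted cubic splines

`rcs_basis()` implements the truncated-power natural cubic spline basis
(Harrell convention): k knots give k − 1 columns, the first linear, with
the function linear beyond the boundary knots. The default knot policy — 4
knots at the 5th/35th/65th/95th exposure percentiles — is the standard
epidemiological default; count and placement are arguments everywhere they
are used, because the source methodology for spline dose–response curves
rarely states them. The nonlinearity test is a design-based Wald test that
all nonlinear basis coefficients vanish (df = k − 2). `rcs_curve()`
evaluates the exponentiated effect over an exposure grid against a
reference value (default: the observed median) with a pointwise band.

## Trend, interaction, Kaplan–Meier, log-rank

The quartile p-trend refits the model with the quartile factor replaced by
a single ordinal term; the Wald p-value of that term is invariant to affine
recoding of the scores. Interaction tests add exposure × modifier product
terms and test them jointly with the design covariance. The product-limit
estimator and the k-sample log-rank statistic use weighted risk/event
totals; with unit weights both reduce exactly to their textbook forms
(verified against independent implementations). For the weighted log-rank,
weights are normalized to mean one so the finite-sample tie-correction
factor (Y − d)/(Y − 1) keeps its usual scale.

## Two-segment (turning-point) Cox model

The log-hazard is modelled as continuous and piecewise-linear in the
exposure: `x` plus `pmax(x − c, 0)`. The breakpoint `c` is chosen by
maximizing the weighted partial likelihood over the grid of observed
exposure values between the 5th and 95th percentiles (interior grid:
boundary breakpoints are artifacts of thin tails). A fit whose best
breakpoint does not beat the single-slope model by the chi-squared(1) 0.95
margin is flagged non-identifiable instead of reporting an arbitrary point.

Per-side hazard ratios come from the model at the selected breakpoint, but
their confidence bounds are the union of the Wald intervals over every
breakpoint in the 95% profile-likelihood set. Simulation showed the naive
conditional-on-selection intervals under-cover precisely when the
breakpoint is mis-selected by one grid step (the flat-side slope then
absorbs part of the sloped segment); widening by the profile set restores
near-nominal joint coverage at the cost of conservatism when the
breakpoint is unambiguous.

## The synthetic cohort

`generate_cohort()` emulates the *structure* of an NHANES-like analytic
sample: sex-shifted right-skewed (log-normal) nutrient intakes with
positive cross-correlations (Gaussian copula, exchangeable latent
correlation 0.3 among the dietary components), zero-inflated alcohol,
peaked BMI and heavy-tailed cotinine, PCE risk-factor distributions around
typical mid-life US values, a stratified design (15 strata × 2 PSUs) with
shifted-lognormal weights independent of the outcome by default (an
informative-weights switch exists to probe design-vs-model divergence),
and linked-mortality columns.

Two deliberate choices make parameter recovery a sharp test. First, the
outcome truths are linked to the **scored** OBS, not the latent component
values: the binary high-risk outcome is drawn from
`logit P = intercept + β·OBS` and survival from an exponential
proportional-hazards model `baseline·exp(γ·OBS)` — so the estimand of the
analysis equals the generator's parameter exactly, and any bias is the
fitter's. Second, survival is exponential by default because censoring
fractions and cumulative mortality then have closed forms (the default
calibration targets roughly a third of participants high-risk and ~20%
mortality over a 16-year administrative horizon, echoing the motivating
study's margins as realism defaults, not as targets).

What the generator does **not** emulate: NHANES variable names and
codebooks, nonresponse and post-stratification, measurement error in 24-h
recalls, within-person day-to-day intake variation, and cluster-level
outcome correlation (outcomes are drawn independently given OBS, so design
and robust variances coincide in truth). Passing recovery tests therefore
demonstrates correctness of the estimators under a clean data-generating
process, not robustness to those real-data complications.

## Problem sizes used by the verification suite

The recovery and calibration checks run at the sizes a desk-scale study of
these estimators needs for the stated tolerances: 200 replicates of
n = 20,000 (cross-sectional OR truth 0.94; CI coverage), 200 replicates of
n = 10,000 with ~20% uniform censoring (HR truth 0.97), 1,000 + 200
replicates of n = 2,000 (nonlinearity-test size and power), 100 replicates
of n = 5,000 (turning-point recovery), and n = 10,000 for the product-limit
closed-form comparison. The censoring design for the cohort recovery draws
dropout times uniformly on (0, horizon) with the horizon set so that about
20% of subjects are censored under the truth.

## Known limitations

- The exclusion cascade attributes each removed row to the *first* rule it
  violates; published flow-chart counts that overlap arithmetically cannot
  be reconciled without the source data, so ledger counts are
  convention-dependent.
- The weighted log-rank is the classic statistic with weighted totals, not
  a replication-based survey log-rank; with strongly informative weights
  its null distribution is approximate.
- Cox ties use the Breslow approximation only.
- The SAS transport (XPT) adapter wraps `foreign::read.xport()` plus a
  column mapping; value recodings (e.g. numeric sex codes) are left to a
  caller-supplied mapping because NHANES codebooks vary by cycle, and the
  binary read path is exercised only when a real XPT file is supplied.
- PCE coefficients are transcribed values; the packaged file's checksum and
  provenance column exist so any re-transcription is a visible, reviewable
  change.
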