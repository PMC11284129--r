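# oxbalance

Oxidative balance score construction and design-based cardiovascular risk
analysis for NHANES-style complex survey data.

## The scientific problem

The oxidative balance score (OBS) is a composite exposure summarizing the
pro-oxidant/antioxidant balance of diet and lifestyle. Twenty components —
16 dietary nutrient intakes and 4 lifestyle variables, of which 5 are
pro-oxidants and 15 antioxidants — are each scored 0–2 and summed:

- every tertile-rule component is split at the sex-specific tertile
  cutpoints `t1`, `t2` (1/3 and 2/3 empirical quantiles within each sex);
  antioxidants score the tertile rank ascending (0, 1, 2), pro-oxidants
  descending (2, 1, 0);
- alcohol is scored by category: abstainer → 2, non-heavy → 1, heavy → 0,
  with heavy defined as ≥ 15 g/day (women) or ≥ 30 g/day (men).

The total OBS ranges 0–40 (dietary sub-score 0–32, lifestyle 0–8); higher
means a more antioxidant-dominant exposure.

Ten-year atherosclerotic cardiovascular disease (ASCVD) risk comes from the
ACC/AHA Pooled Cohort Equations: sex- and race-specific proportional-hazards
equations with risk

&nbsp;&nbsp;&nbsp;&nbsp;`risk = 1 − S₁₀ ^ exp(LP − mean LP)`

where the linear predictor LP combines ln(age), ln(lipids),
treatment-specific ln(SBP), smoking, diabetes and age interactions.
Predicted risk ≥ 7.5% defines *high ASCVD risk*.

The package estimates the association of OBS (total, dietary, lifestyle)
with high ASCVD risk cross-sectionally and with all-cause/CVD mortality in
the high-risk subgroup, honouring the survey design throughout:
survey-weighted logistic and Cox regression with Taylor-linearized
stratified-cluster (stratum/PSU) variance, restricted cubic splines with
design-based nonlinearity tests, quartile trend tests, subgroup interaction
tests, weighted Kaplan–Meier curves with a weighted log-rank test, and a
two-segment (turning-point) Cox model in the exposure. A synthetic
NHANES-like cohort generator with known ground truth (logistic truth in the
*scored* OBS; exponential proportional-hazards survival) makes every stage
testable without any data download.

## Worked example

```r
library(oxbalance)

cohort   <- generate_cohort(cohort_config(n = 5000, seed = 2026))
analytic <- apply_exclusions(add_ascvd_risk(compute_obs(cohort)))

res <- run_cross_sectional(analytic$cohort, exposures = "obs_total",
                           forms = c("continuous", "quartile"),
                           models = c(1, 3))
res
#>    exposure  form       model term        level estimate conf.low conf.high
#>  1 obs_total continuous     1 obs_total   <NA>     0.948    0.935     0.960
#>  2 obs_total quartile       1 obs_total_q Q1       1       NA        NA
#>  3 obs_total quartile       1 obs_total_q Q2       0.761    0.591     0.980
#>  4 obs_total quartile       1 obs_total_q Q3       0.615    0.479     0.788
#>  5 obs_total quartile       1 obs_total_q Q4       0.462    0.367     0.581
#>  6 obs_total continuous     3 obs_total   <NA>     0.948    0.936     0.961
#>  ...
```

The continuous rows are odds ratios per OBS unit for high ASCVD risk
(Model 1 unadjusted, Model 3 fully adjusted): here the generator's truth was
OR 0.94 per unit, and the fitted 0.948 (95% CI 0.935–0.960) recovers it
within sampling error. Quartile rows give each quartile's OR against Q1
(always exactly 1, the reference), with a shared p-trend — the monotone
decline from 0.76 to 0.46 mirrors the dose–response the continuous model
summarizes.

Mortality in the high-risk subgroup, with design-based standard errors:

```r
high <- dplyr::filter(analytic$cohort, ascvd_high)
fit  <- fit_weighted_cox(high, Surv(follow_months, death) ~ obs_total)
tidy(fit, exponentiate = TRUE)
#>   term      estimate std.error statistic p.value conf.low conf.high
#> 1 obs_total    0.987    0.0118     -1.07   0.284    0.965      1.01
```

i.e. a hazard ratio of 0.987 per OBS unit (truth 0.97; n here is only the
~1,600 high-risk rows, so the CI is wide). `run_cohort()` wraps the full
mortality analysis (both outcomes, all exposure forms, Kaplan–Meier by
quartile, log-rank, and the turning-point model); `run_subgroups()` adds the
stratified estimates with interaction p-values; `write_report()` serializes
everything. `autoplot()` methods plot Kaplan–Meier and spline dose–response
curves.

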