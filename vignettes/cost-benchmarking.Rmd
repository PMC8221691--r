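---
title: "Benchmarking home care models on societal costs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking home care models on societal costs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(carecost)
```

## The problem

Home-care organizations arrange care for older adults in very different
ways, and those arrangements plausibly shift costs between hospital
care, professional home care and unpaid informal care.  `carecost`
implements a benchmarking pipeline for this question: estimate 6-month
*societal* costs per client (all resource use, whoever pays) from
interRAI-HC style assessment data, classify organizations into *care
models* from three core elements of care delivery, and compare
case-mix-adjusted mean costs between care models.

The unit of analysis is the client.  Each client is assessed at
baseline and at 6 months; each assessment reports resource-use
quantities over item-specific recall periods (90 days for
hospitalization, emergency-room and physician visits; 7 days for home
care and therapists; 3 days for informal care), plus validated clinical
scales: CPS (cognition, 0–6), DRS (depression, 0–14), ADLH (ADL
hierarchy, 0–6), iADL (instrumental ADL, 0–48) and CHESS (health
instability, 0–5).

## Costing model

Quantities are scaled to a common quarter,
`quantity * 91 / recall_days`, valued with one uniform standard-cost
price table (so between-model differences reflect utilization, not
national price levels), and accumulated into seven categories:
hospital admissions, emergency/physician visits, other healthcare
services, supportive care services, institutional care, home care and
informal care.  Informal care hours are valued at the wage of a legally
employed cleaner (proxy-good method).  Hospital nights are admissions
times the country-mean length of stay, except in the recorded-days
country (Belgium in the source instrument), where assessments register
total admission days directly.

The 6-month total interpolates the two assessed quarters with weights
0.5 and 1.5: the first three months are costed at the average of the
two assessed rates, the second three months at the month-6 rate.  The
societal total is the sum of the seven categories; the healthcare
perspective simply excludes informal care.

**Transitions.**  Clients who die or are institutionalized between
assessments have no month-6 assessment.  The event is placed halfway
through the 182-day window: community costs accrue at the baseline rate
for the first 91 days, and afterwards costs are zero (death) or the
facility's per-diem (institutionalization).  Because the package keeps
the interpolation identity `total = 0.5 q1 + 1.5 q2` exact for *every*
client, `apply_transition_rules()` returns the *effective* month-6
quarterly costs implied by that schedule rather than literal
observations; a day-by-day accrual simulation over the 182 days is used
in the test suite to pin these semantics.  Note the asymmetry, which is
deliberate: while a client is in care the first quarter accrues the
*average* of the two assessed rates (both assessments inform it), but
after a mid-window death or admission only the baseline rate is
observable, so the pre-event accrual uses the baseline rate alone.
Clients discharged from care or lost to follow-up get *missing*
month-6 costs — their costs are imputed, never extrapolated.

## Care-model classification

Organizations answer a 15-item questionnaire: 6 items on patient-centred
care (PCC), 5 on availability of specialized professionals (ASP), 4 on
monitoring of care performance (MCP).  Element scores are item means;
levels are dichotomized at per-element thresholds and the level pattern
(PCC, ASP, MCP) maps to a care model:

| pattern | model |
|---|---|
| H H H | CM1 |
| H L H | CM2 |
| L L H | CM3 |
| H H L | CM4 |
| L H H | CM5 (flagged, excluded) |
| other low-MCP | CM6 (flagged, excluded) |

The exact dichotomization rule used in the source instrument's
derivation study is not publicly specified, so the package defaults to
the only symmetric choice — the scale midpoint — and makes the
thresholds arguments; scores exactly at a threshold count as high
(fixed, documented tie-break).  The CM5/CM6 residual rule is likewise a
declared stand-in, and such organizations are flagged `excluded` so the
comparison drops them (the models were excluded from benchmarking for
lack of respondents).

## Missing data and pooling

Missing month-6 cost data are imputed by chained equations with
predictive mean matching (PMM), `m = 10` datasets by default.  The
imputer is implemented in the package and operates at the *wave level*
(the quarterly category costs `q1_*`, `q2_*`), before the 6-month
interpolation, so the interpolation identity holds in every completed
dataset.  Each update regresses the observed values of one cost
variable on the fully observed baseline case-mix covariates plus the
other cost variables at their current values, and fills each missing
cell with a uniform draw from the 5 observed donors closest in
predicted mean — so imputations always stay within the observed
support, which is what makes PMM suitable for right-skewed costs.  The
matching is *proper*: the missing-cell predictions use a Bayesian draw
of the regression parameters (scaled inverse-chi-squared error
variance, normal coefficients), so the m datasets carry genuine
between-imputation variability rather than m re-runs of one fit.  The
update order is the declared column order and the whole procedure is
deterministic under its seed.  Downstream estimates are pooled by
Rubin's rules: pooled estimate = mean of per-dataset estimates, total
variance `T = W + (1 + 1/m) B`.

## Adjusted comparison and the BCa bootstrap

Within each completed dataset the 6-month cost is regressed (OLS) on
care-model dummies plus eight case-mix covariates: age, sex, living
alone, CPS, DRS, ADLH, iADL, CHESS.  Covariates first pass a Spearman
collinearity screen (cutoff `|rho| > 0.4`; of a flagged pair the
lower-priority member is dropped, both are reported).  The dummy
coefficients are adjusted mean cost differences versus the reference
model — by default the model with the lowest unadjusted mean cost.

Because cost data are strongly right-skewed, confidence intervals use
the bias-corrected accelerated (BCa) bootstrap, resampling *clients*
with replacement (B = 5000 by default; resamples missing a care model
are redrawn).  The package fixes the BCa conventions explicitly: the
bias-correction `z0` counts ties with the point estimate as half; the
acceleration comes from jackknife skewness (computed by exact OLS
leave-one-out downdating, so no refits are needed); endpoints are
type-7 empirical quantiles of the resample distribution.  With `z0 = 0`
and `a = 0` the interval reduces to the percentile interval, and a
degenerate resample distribution returns the point value with a
warning.

**Composing imputation and bootstrap.**  How BCa intervals should be
pooled over imputed datasets has no canonical answer.  The package
bootstraps within each imputed dataset and pools point estimates by
Rubin's rules, with the bootstrap variances as within-imputation
variances `W`.  For the pooled interval it averages the per-imputation
BCa *offsets* (bound minus estimate) and rescales them around the
pooled estimate by `sqrt(T / W)`, where `T = W + (1 + 1/m) B` is
Rubin's total variance.  The rescaling matters: simply averaging the
per-imputation bounds discards the between-imputation component `B`
and makes the pooled interval anti-conservative — in the package's own
calibration runs that naive rule inflated the empirical type-I error
to about twice the nominal level, while the rescaled rule brings it
back to nominal.  When the imputed datasets agree (`B = 0`) the rule
reduces exactly to bound-averaging.  The composition is isolated in
`compare_care_models()` so the alternative (bootstrap-then-impute)
could be swapped without touching anything else.  Clustering of clients within organizations is deliberately *not*
reflected in the variance machinery, matching the analysis the pipeline
reproduces; with few, heterogeneous organizations per model this can
understate uncertainty.  Country of residence is not a default
covariate (it can be added through the `covariates` argument).

## The synthetic-cohort generator

No client-level dataset ships with the package, so every stage is
validated against generated cohorts with known ground truth.  The
generator's defaults describe the study population the package targets:
three care models with 6/3/9 organizations and roughly 1330/310/420
clients, countries assigned per model, mean 6-month societal costs near
EUR 16 000–19 000, injected adjusted differences of +2230 (CM2 vs CM1)
and −322 (CM3 vs CM1), 2% deaths and 3% institutionalizations over the
window, and item missingness calibrated so that roughly 29% of clients
miss at least one utilization item.

Mechanics worth knowing when interpreting test results:

* Each client's expected 6-month societal cost is
  `base + effect[model] + 3200 * ADLH + 1500 * CHESS` (defaults; both
  coefficients and the scale distributions are scenario arguments).
  Case-mix distributions differ *by model* — CM2 clients are markedly
  less dependent — which is exactly the confounding the adjusted
  analysis must remove: with the defaults the raw CM2−CM1 contrast is
  biased several thousand euros below the injected effect.
* Skew is induced at the quantity level: counts (admissions, visits)
  are Poisson, minutes (home, therapist, informal care) are Gamma with
  shape 0.8, all mean-calibrated through the price table, so expected
  valued costs are exactly linear in the scenario parameters and the
  per-model sample mean converges to
  `expected_model_costs(scenario)` (checked at n = 5000 within 3
  Monte-Carlo standard errors).
* Transitions record only the month-6 status, as the real instrument
  does; the halfway rule is the costing engine's job, not the
  generator's.
* Missingness is MCAR or MAR (logistic in ADLH), per item cell or per
  wave; "missing 6-month cost data" scenarios delete the whole month-6
  item set of a client.

What the generator does *not* emulate: country-specific utilization
patterns, within-client correlation of quantities across waves beyond
shared case mix, organization-level random effects, or measurement
error in the scales.  Passing tests therefore demonstrate that the
pipeline recovers what it injects under its own assumptions — not that
those assumptions hold in any particular real dataset.

## Numerical choices and degenerate inputs

* No premature rounding anywhere in costing; tables round to whole
  currency units for display only.
* Scale scores are ordinal integers; non-integer input is rejected,
  never rounded.  Missing quantities stay `NA`, never 0.
* Currency is a label; no exchange-rate conversion (uniform price sets
  are the point).  Two named price tables can coexist for the
  price-swap sensitivity analysis, and costing is exactly homogeneous
  of degree 1 in the price table.
* `z0` clamps (with a warning) when all bootstrap replicates fall on
  one side of the estimate; a constant resample distribution returns a
  zero-width interval.
* Rank-deficient designs fail naming the offending columns; a
  100%-missing cost variable fails for lack of donors; an empty care
  model group is flagged and excluded from aggregation.

## Operating characteristics

`simulate_type1_error()` and `simulate_coverage()` run the whole
pipeline over repeated cohorts: 200 null cohorts (n = 600, three
models, wave-level MCAR 10% on the month-6 assessment, m = 5, B = 500)
for the empirical type-I error of the CM2−CM1 interval, and 200 cohorts
with an injected difference of 2230 (n = 600, two models, B = 500) for
empirical coverage.  These problem sizes are the package's calibration
defaults; they keep a full run in minutes on one core while leaving the
binomial Monte-Carlo error around ±0.015 for a 5% rate.
`scripts/acceptance.R` reruns both from scratch and writes the two
rates as JSON.

```{r, eval = FALSE}
# a full analysis, end to end, on synthetic data
sc  <- simulation_scenario(seed = 1)
g   <- generate_cohort(sc)
asg <- assign_care_models(g$organizations)
bd  <- client_costs(g$cohort, carecost_prices("dutch_reference"))
imp <- impute_costs(bd, m = 10, seed = 1)
cmp <- compare_care_models(imp, assignments = asg, B = 5000, seed = 1)
summary(cmp)
report <- build_report(imp$datasets[[1]], cmp, carecost_config(),
                       assignments = asg)
print(report)
plot(cmp)
```

## Known limitations

* The shipped price tables are illustrative synthetic values; the
  published standard-cost tables the method was designed around are not
  reproduced here.  Substantive use requires a real price table.
* Whether discharged/lost clients' second-quarter costs should be
  extrapolated instead of imputed is an open question in the source
  method; this package imputes.
* The imputation level (wave-level category costs) is a declared
  choice; imputing 6-month totals directly is also defensible and would
  give slightly different pooled variances.
* Organization-level clustering is ignored in the variance machinery
  (see above).
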