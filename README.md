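# carecost

Societal cost benchmarking of home care models for older adults.

Home-care organizations arrange care differently — more or less
patient-centred, with or without specialized professionals, with or
without systematic monitoring of care performance — and those
arrangements shift costs between hospitals, professional home care and
unpaid informal care.  `carecost` implements the full analysis pipeline
for benchmarking *care models* on 6-month societal costs per client
from interRAI-HC style assessment data:

1. **Costing engine** — resource-use quantities reported over
   item-specific recall periods (90/7/3 days) are scaled to a 91-day
   quarter, valued with one uniform standard-cost price table, and
   accumulated into seven categories (hospital, emergency/physician
   visits, other healthcare, supportive care, institutional care, home
   care, informal care).  The 6-month total interpolates the two
   assessed quarters as `0.5 × baseline + 1.5 × month-6`.  Clients who
   die or are institutionalized mid-window are costed by the halfway
   rule (community costs to day 91, then zero or the facility
   per-diem); informal care is valued by the proxy-good method.
2. **Care-model classifier** — 15 organizational questionnaire items →
   three element scores (patient-centred care, availability of
   specialized professionals, monitoring of care performance) →
   care models CM1–CM6 by dichotomized level patterns.
3. **Imputation** — missing 6-month cost data imputed by chained
   equations with proper predictive mean matching (m = 10 datasets),
   pooled by Rubin's rules.
4. **Inference** — OLS of cost on care-model dummies plus eight
   case-mix covariates (age, sex, living alone, CPS, DRS, ADLH, iADL,
   CHESS; Spearman collinearity screen at |rho| > 0.4), with
   bias-corrected accelerated (BCa) bootstrap confidence intervals at
   the client level (B = 5000), pooled across imputations.
5. **Synthetic cohorts** — a generator with known ground truth
   (injected model effects, case-mix confounding through ADLH/CHESS,
   right-skewed Poisson/Gamma quantities, wave-2 attrition, MCAR/MAR
   missingness) so every stage is testable without any data download.

The estimand is the case-mix-adjusted mean cost difference between care
models: in `E[cost] = β0 + Σg βg 1{model = g} + γ'x`, each `βg` is the
adjusted difference versus the reference model (the lowest-cost model).

## Worked example

```r
library(carecost)

sc  <- simulation_scenario(seed = 1)        # defaults: 3 care models,
g   <- generate_cohort(sc)                  # ~2000 clients, effects
asg <- assign_care_models(g$organizations)  # +2230 (CM2), -322 (CM3)
bd  <- client_costs(g$cohort, carecost_prices("dutch_reference"))
imp <- impute_costs(bd, m = 10, seed = 1)
cmp <- compare_care_models(imp, assignments = asg, B = 1000, seed = 1)
cmp
```

```
<care_model_comparison> societal perspective, 2058 clients, reference: CM2
  m = 10 imputations, B = 1000 bootstrap replications, 95% BCa intervals
  contrast estimate   ci_low ci_high     se
 CM1 - CM2 -1175.20 -2692.95  373.75 793.29
 CM3 - CM2 -2482.41 -4153.80 -837.49 852.44
 CM3 - CM1 -1307.21 -2475.28 -144.11 599.35
```

The generator injected adjusted differences of −2230 (CM1 − CM2),
−2552 (CM3 − CM2) and −322 (CM3 − CM1); at this cohort size the
pooled standard errors are 600–850, and the three estimates land
within 1.3, 0.1 and 1.6 SE of those truths — one seed's ordinary
sampling variability (the repeated-cohort calibration below is the
systematic check).  Note the case-mix flip the adjustment corrects:
CM2 serves the least dependent clients, so its *unadjusted* mean cost
is the lowest (which is why it is the reference) even though its
adjusted cost is the highest.

```r
report <- build_report(imp$datasets[[1]], cmp, carecost_config(),
                       assignments = asg)
report            # per-model means, category shares, informal:home ratios
plot(cmp)         # forest plot of adjusted differences
```

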