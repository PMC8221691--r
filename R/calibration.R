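# Operating characteristics of the full pipeline on repeated synthetic
# cohorts: empirical type-I error under a null scenario and empirical
# coverage under a known injected effect.  These drive the package's own
# calibration checks; both run the same stages a real analysis uses
# (generation, costing, imputation where applicable, adjusted
# regression, BCa bootstrap).

# Scenario for repeated-cohort simulations: 3 (or 2) care models with
# the default case-mix confounding, no transitions (every client's
# 6-month cost is defined), optional wave-level MCAR on the month-6
# assessment.
sim_scenario <- function(models = c("CM1", "CM2", "CM3"),
                         n_per_model = 200, effects = NULL,
                         missing_rate = 0, seed = 1L) {
  if (is.null(effects))
    effects <- stats::setNames(rep(0, length(models)), models)
  simulation_scenario(
    n_orgs_per_model = stats::setNames(rep(2L, length(models)), models),
    n_clients_per_org = stats::setNames(rep(n_per_model / 2, length(models)),
                                        models),
    countries_by_model = stats::setNames(
      list(c("IT", "NL"), c("NL", "FI"), "GE")[seq_along(models)],
      models),
    true_model_effects = effects,
    transition_probs = c(deceased = 0, institutionalized = 0,
                         discharged = 0, lost = 0),
    missingness = list(mechanism = "MCAR", rate = missing_rate,
                       waves = "month6", unit = "wave"),
    seed = seed)
}

#' Empirical type-I error of the adjusted between-model comparison
#'
#' Generates `n_cohorts` synthetic cohorts under a null scenario (three
#' care models, all true model effects zero, case-mix confounding
#' active, wave-level MCAR missingness on the month-6 assessment), runs
#' the full pipeline -- costing, chained-equation PMM imputation with
#' `m` datasets, case-mix-adjusted regression and the client-level BCa
#' bootstrap -- and reports the fraction of pooled confidence intervals
#' for the CM2 - CM1 adjusted cost difference that exclude zero.  With
#' a calibrated pipeline this fraction estimates the nominal `alpha`.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param n_per_model Clients per care model per cohort.
#' @param missing_rate Wave-level MCAR rate on the month-6 assessment.
#' @param m Imputed datasets per cohort.
#' @param B Bootstrap replications per imputed dataset.
#' @param alpha Nominal significance level.
#' @param maxit Chained-equation iterations (missingness is confined to
#'   the month-6 cost variables, whose predictors are complete, so few
#'   passes are needed).
#' @param seed Master seed; cohort `i` uses `seed + i`.
#' @return List with `rejection_rate`, `n_cohorts`, and the per-cohort
#'   interval table.
#' @export
simulate_type1_error <- function(n_cohorts = 200, n_per_model = 200,
                                 missing_rate = 0.10, m = 5, B = 500,
                                 alpha = 0.05, maxit = 2, seed = 1L) {
  prices <- carecost_prices("dutch_reference")
  res <- matrix(NA_real_, n_cohorts, 3,
                dimnames = list(NULL, c("estimate", "lo", "hi")))
  for (i in seq_len(n_cohorts)) {
    sc <- sim_scenario(n_per_model = n_per_model,
                       missing_rate = missing_rate, seed = seed + i)
    g <- generate_cohort(sc, prices)
    bd <- client_costs(g$cohort, prices)
    bd$model <- g$truth$model_by_client[bd$client_id]
    imp <- impute_costs(bd, m = m, maxit = maxit, seed = seed + i)
    cmp <- compare_care_models(imp, reference = "CM1", B = B,
                               alpha = alpha, seed = seed + i)
    k <- match("CM2 - CM1", cmp$contrasts$contrast)
    res[i, ] <- c(cmp$contrasts$estimate[k], cmp$contrasts$ci_low[k],
                  cmp$contrasts$ci_high[k])
  }
  reject <- res[, "lo"] > 0 | res[, "hi"] < 0
  list(rejection_rate = mean(reject), n_cohorts = n_cohorts,
       intervals = as.data.frame(res))
}

#' Empirical coverage of the BCa interval for an injected difference
#'
#' Generates `n_cohorts` synthetic two-model cohorts with a known
#' injected adjusted cost difference `delta` (right-skewed costs,
#' case-mix confounding, no missingness), computes the BCa interval for
#' the adjusted CM2 - CM1 difference per cohort, and reports the
#' fraction of intervals containing `delta`.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param n_per_model Clients per care model per cohort.
#' @param delta Injected adjusted difference (money).
#' @param B Bootstrap replications.
#' @param alpha Nominal significance level.
#' @param seed Master seed; cohort `i` uses `seed + i`.
#' @return List with `coverage` (fraction in `[0, 1]`), `n_cohorts`,
#'   `delta` and the per-cohort interval table.
#' @export
simulate_coverage <- function(n_cohorts = 200, n_per_model = 300,
                              delta = 2230, B = 500, alpha = 0.05,
                              seed = 1L) {
  prices <- carecost_prices("dutch_reference")
  res <- matrix(NA_real_, n_cohorts, 3,
                dimnames = list(NULL, c("estimate", "lo", "hi")))
  for (i in seq_len(n_cohorts)) {
    sc <- sim_scenario(models = c("CM1", "CM2"),
                       n_per_model = n_per_model,
                       effects = c(CM1 = 0, CM2 = delta),
                       seed = seed + i)
    g <- generate_cohort(sc, prices)
    bd <- client_costs(g$cohort, prices)
    bd$model <- g$truth$model_by_client[bd$client_id]
    cmp <- compare_care_models(bd, reference = "CM1", B = B,
                               alpha = alpha, seed = seed + i)
    k <- match("CM2 - CM1", cmp$contrasts$contrast)
    res[i, ] <- c(cmp$contrasts$estimate[k], cmp$contrasts$ci_low[k],
                  cmp$contrasts$ci_high[k])
  }
  covered <- res[, "lo"] <= delta & res[, "hi"] >= delta
  list(coverage = mean(covered), n_cohorts = n_cohorts, delta = delta,
       intervals = as.data.frame(res))
}
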