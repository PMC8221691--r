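# Synthetic-cohort generator: reproducibility, boundary scenarios,
# missingness mechanisms, and marginal control of the injected costs.

test_that("degenerate scenario yields two complete waves per client", {
  g <- generate_cohort(quick_scenario(n_per_org = 20, seed = 5))
  co <- g$cohort
  expect_identical(nrow(co), 80L)   # 2 models x 20 clients x 2 waves
  expect_true(all(table(co$client_id) == 2))
  expect_true(all(co$status[co$wave == "month6"] == "in_care"))
  # complete: every item observed except recorded-days, which only the
  # recorded-days country registers
  items <- setdiff(carecost_items()$item_key, "hosp_days")
  expect_false(anyNA(co[items]))
})

test_that("certain death removes all wave-2 quantities", {
  sc <- quick_scenario(n_per_org = 10, seed = 2,
                       transition_probs = c(deceased = 1,
                                            institutionalized = 0,
                                            discharged = 0, lost = 0))
  co <- generate_cohort(sc)$cohort
  w2 <- co[co$wave == "month6", ]
  expect_true(all(w2$status == "deceased"))
  expect_true(all(is.na(w2[carecost_items()$item_key])))
})

test_that("generated cohorts pass data-model validation and reproduce under a seed", {
  sc <- quick_scenario(n_per_org = 25, missing_rate = 0.1, seed = 11,
                       transition_probs = c(deceased = 0.05,
                                            institutionalized = 0.05,
                                            discharged = 0.02,
                                            lost = 0.02))
  g1 <- generate_cohort(sc)
  g2 <- generate_cohort(sc)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$organizations, g2$organizations)
  expect_silent(validate_cohort(g1$cohort))
  g3 <- generate_cohort(quick_scenario(n_per_org = 25,
                                       missing_rate = 0.1, seed = 12))
  expect_false(identical(g1$cohort, g3$cohort))
})

test_that("organization tables classify back to the intended care model", {
  sc <- quick_scenario(models = c("CM1", "CM2", "CM3"),
                       n_per_org = 5, seed = 7)
  g <- generate_cohort(sc)
  asg <- assign_care_models(g$organizations)
  intended <- vapply(strsplit(asg$org_id, "_"), `[`, character(1), 1)
  expect_identical(asg$model, intended)
})

test_that("MCAR missingness matches the per-item Bernoulli model", {
  rate <- 0.29
  sc <- quick_scenario(n_per_org = 1000, missing_rate = rate, seed = 19)
  co <- generate_cohort(sc)$cohort
  items <- carecost_items()$item_key
  # brute-force expectation: each client's eligible cells are the item
  # cells a missingness-free replicate observes; P(>=1 missing) =
  # 1 - (1-rate)^k per client
  co0 <- generate_cohort(quick_scenario(n_per_org = 1000,
                                        missing_rate = 0,
                                        seed = 19))$cohort
  k_eligible <- tapply(rowSums(!is.na(co0[items])), co0$client_id, sum)
  p_implied <- mean(1 - (1 - rate)^k_eligible)

  n_miss <- tapply(rowSums(is.na(co[items])) -
                   rowSums(is.na(co0[items])), co$client_id, sum)
  p_obs <- mean(n_miss >= 1)
  mc_se <- sqrt(p_implied * (1 - p_implied) / length(k_eligible))
  expect_lt(abs(p_obs - p_implied), 3 * mc_se + 1e-12)
})

test_that("missingness boundary rates behave exactly", {
  co <- generate_cohort(quick_scenario(n_per_org = 15, seed = 3))$cohort
  expect_identical(inject_missingness(co, "MCAR", rate = 0), co)
  all_gone <- inject_missingness(co, "MCAR", rate = 1, seed = 1)
  items <- carecost_items()$item_key
  expect_true(all(is.na(all_gone[items])))
  expect_error(inject_missingness(co, "MCAR", rate = 1.2), "rate")
  expect_error(inject_missingness(co, "teleport", rate = 0.1))
})

test_that("MAR missingness increases monotonically with ADLH and matches the logistic model", {
  sc <- quick_scenario(n_per_org = 4000, seed = 23)
  co <- generate_cohort(sc)$cohort
  rate <- 0.15; coef <- 0.5
  mar <- inject_missingness(co, "MAR", rate = rate, mar_coef = coef,
                            seed = 77)
  # stratify cell-level missingness by adlh; informal_min is observed
  # everywhere pre-injection
  strata <- sort(unique(co$adlh))
  emp <- vapply(strata, function(a)
    mean(is.na(mar$informal_min[mar$adlh == a])), numeric(1))
  theo <- plogis(qlogis(rate) + coef * (strata - 3))
  n_str <- vapply(strata, function(a) sum(co$adlh == a), numeric(1))
  keep <- n_str >= 200
  expect_true(all(diff(emp[keep]) > 0))
  expect_true(all(abs(emp[keep] - theo[keep]) <
                  3 * sqrt(theo[keep] * (1 - theo[keep]) / n_str[keep])))
})

test_that("generated mean societal cost per model matches the scenario's implied expectation", {
  sc <- quick_scenario(models = c("CM1", "CM2"), n_per_org = 2500,
                       effects = c(CM1 = 0, CM2 = 2230), seed = 31)
  g <- generate_cohort(sc)
  bd <- client_costs(g$cohort, carecost_prices("dutch_reference"))
  bd$model <- g$truth$model_by_client[bd$client_id]
  implied <- expected_model_costs(sc)
  for (mdl in c("CM1", "CM2")) {
    tot <- bd$total_societal_6m[bd$model == mdl]
    mc_se <- sd(tot) / sqrt(length(tot))
    expect_lt(abs(mean(tot) - implied[[mdl]]), 3 * mc_se,
              label = paste("model", mdl))
  }
})

test_that("infeasible scenarios are rejected", {
  expect_error(quick_scenario(effects = c(CM1 = 0, CM2 = -20000)),
               "infeasible")
  expect_error(
    simulation_scenario(transition_probs = c(deceased = 0.6,
                                             institutionalized = 0.6,
                                             discharged = 0, lost = 0)),
    "sum to <= 1")
})
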