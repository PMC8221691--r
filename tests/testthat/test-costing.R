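# Costing engine: scaling, hospital nights, valuation, transition
# rules, interpolation and aggregation.

test_that("recall-period quantities scale to the 91-day quarter", {
  expect_identical(scale_to_quarter(0, 90), 0)
  expect_equal(scale_to_quarter(7, 7), 91)         # 7 hours/week
  expect_equal(scale_to_quarter(2, 90), 2 * 91 / 90)
  expect_true(is.na(scale_to_quarter(NA, 90)))
  expect_error(scale_to_quarter(-1, 90), ">= 0")
})

test_that("hospital nights use recorded days in the recorded-days country, LOS elsewhere", {
  pr <- test_prices()
  expect_equal(hospital_nights(3, "BE", recorded_days = 12, prices = pr),
               12)
  expect_equal(hospital_nights(2, "NL", prices = pr), 16)   # LOS 8.0
  expect_equal(hospital_nights(0, "IT", prices = pr), 0)
  expect_error(hospital_nights(1, "XX", prices = pr),
               "no hospital length-of-stay entry")
})

test_that("wave valuation equals an item-by-item hand computation", {
  pr <- test_prices()
  zero <- cohort_row()
  expect_true(all(value_wave(zero, pr) == 0))

  # 7 hours of home care per week -> 91 hours per quarter at 30/hour
  hc <- cohort_row(home_care_min = 7 * 60)
  expect_equal(unname(value_wave(hc, pr)[, "home_care"]), c(91 * 30))

  mixed <- cohort_row(hosp_events = 2, er_visits = 1, phys_visits = 3,
                      home_care_min = 420, informal_min = 90)
  v <- value_wave(mixed, pr)
  # brute force, item by item
  expect_equal(unname(v[, "hospital"]), c(2 * 8 * 91 / 90 * 100))
  expect_equal(unname(v[, "visits"]), c(1 * 91 / 90 * 50 + 3 * 91 / 90 * 10))
  expect_equal(unname(v[, "home_care"]), c(420 / 60 * 91 / 7 * 30))
  expect_equal(unname(v[, "informal"]), c(90 / 60 * 91 / 3 * 12))
  expect_equal(unname(v[, "institutional"]), c(0))

  # missing quantity propagates to its category only
  part <- cohort_row(er_visits = NA, home_care_min = 60)
  vp <- value_wave(part, pr)
  expect_true(is.na(vp[, "visits"]))
  expect_false(is.na(vp[, "home_care"]))
})

test_that("six-month interpolation uses the 0.5/1.5 weights", {
  expect_identical(six_month_cost(0, 0), 0)
  expect_equal(six_month_cost(1234, 1234), 2 * 1234)
  expect_equal(six_month_cost(1000, 2000), 3500)
})

test_that("transition rules reproduce the day-by-day accrual schedule", {
  pr <- test_prices()
  cfg <- carecost_config()
  cats <- cost_categories()
  set.seed(123)
  for (r in 1:25) {
    q1 <- setNames(c(runif(4, 0, 3000), 0, runif(2, 0, 5000)), cats)
    q2 <- setNames(c(runif(4, 0, 3000), 0, runif(2, 0, 5000)), cats)
    for (st in c("in_care", "deceased", "institutionalized")) {
      adj <- apply_transition_rules(
        t(as.matrix(q1)), t(as.matrix(q2)), st,
        facility = "nursing_home", prices = pr, config = cfg)
      got <- six_month_cost(q1, adj[1, ])
      want <- oracle_day_accrual(as.list(q1), as.list(q2), st,
                                 per_diem = pr$facility_per_diem[["nursing_home"]])
      expect_equal(unname(got), unname(want[cats]), tolerance = 1e-10)
    }
  }
})

test_that("deceased clients accrue zero after the midpoint; the lost are missing", {
  pr <- test_prices()
  q1 <- matrix(1000, 1, 7, dimnames = list(NULL, cost_categories()))
  q1[, "institutional"] <- 0
  q2 <- q1
  dead <- apply_transition_rules(q1, q2, "deceased", prices = pr,
                                 config = carecost_config())
  # 6-month total = one baseline quarter only (community until day 91)
  expect_equal(unname(six_month_cost(q1[, "home_care"], dead[, "home_care"])),
               1000)
  lost <- apply_transition_rules(q1, q2, "lost", prices = pr,
                                 config = carecost_config())
  expect_true(all(is.na(lost)))
  expect_error(apply_transition_rules(q1, q2, "institutionalized",
                                      facility = "castle", prices = pr,
                                      config = carecost_config()),
               "no facility per-diem")
})

test_that("totals are conserved and the healthcare perspective is dominated", {
  sc <- quick_scenario(n_per_org = 60, seed = 13,
                       transition_probs = c(deceased = 0.05,
                                            institutionalized = 0.05,
                                            discharged = 0.02,
                                            lost = 0.02))
  g <- generate_cohort(sc)
  bd <- client_costs(g$cohort, test_prices())
  c6m <- as.matrix(bd[paste0("c6m_", cost_categories())])
  ok <- complete.cases(c6m)
  expect_true(any(ok))
  expect_equal(bd$total_societal_6m[ok], rowSums(c6m[ok, , drop = FALSE]))
  expect_equal(bd$total_healthcare_6m[ok],
               bd$total_societal_6m[ok] - bd$c6m_informal[ok])
  expect_true(all(bd$total_healthcare_6m[ok] <=
                  bd$total_societal_6m[ok] + 1e-12))
  expect_true(all(c6m[ok, ] >= 0))
})

test_that("costs are homogeneous of degree one in prices", {
  sc <- quick_scenario(n_per_org = 40, seed = 17)
  g <- generate_cohort(sc)
  pr <- test_prices()
  bd1 <- client_costs(g$cohort, pr)
  bd2 <- client_costs(g$cohort, scale_prices(pr, 3))
  expect_equal(bd2$total_societal_6m, 3 * bd1$total_societal_6m,
               tolerance = 1e-12)
  expect_equal(bd2$c6m_hospital, 3 * bd1$c6m_hospital, tolerance = 1e-12)
})

test_that("aggregation reports means, shares and the informal:home ratio", {
  pr <- test_prices()
  # one client: group mean equals that client's total
  co <- two_wave_cohort(1, home_care_min = 60, informal_min = 180)
  bd <- client_costs(co, pr)
  bd$model <- "CM1"
  agg <- aggregate_costs(bd)
  expect_equal(agg$total_mean, bd$total_societal_6m)
  expect_equal(agg$n, 1L)

  # constructed informal = 3 x home-care cost: 1 home hour and 7.5
  # informal hours per recall gives quarterly 91*30 vs 3*91*30
  co <- two_wave_cohort(4, home_care_min = 7 * 60,
                        informal_min = 3 * 3 * (30 / 12) * 60)
  bd <- client_costs(co, pr)
  bd$model <- "CM1"
  agg <- aggregate_costs(bd)
  expect_equal(agg$informal_home_ratio, 3)

  # healthcare perspective: total = societal - informal, per client
  hc <- aggregate_costs(bd, perspective = "healthcare")
  expect_equal(hc$total_mean,
               mean(bd$total_societal_6m - bd$c6m_informal))
  expect_true(is.na(hc$informal_home_ratio))
  shares <- as.numeric(agg[grep("^share_", names(agg))])
  expect_equal(sum(shares), 100)
})
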