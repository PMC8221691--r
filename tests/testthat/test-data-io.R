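# Cohort and price-table I/O: validation totality and round-tripping.

test_that("cohort validation rejects rows violating the data model", {
  ok <- two_wave_cohort(2)
  expect_silent(validate_cohort(ok))

  bad <- ok; bad$cps[1] <- 7
  expect_error(validate_cohort(bad), "cps out of range \\[0,6\\]")
  bad <- ok; bad$drs[2] <- 15
  expect_error(validate_cohort(bad), "drs out of range \\[0,14\\]")
  bad <- ok; bad$iadl[1] <- 49
  expect_error(validate_cohort(bad), "iadl out of range \\[0,48\\]")
  bad <- ok; bad$chess[1] <- 2.5
  expect_error(validate_cohort(bad), "chess must be an integer")
  bad <- ok; bad$age[1] <- 64
  expect_error(validate_cohort(bad), "age must be >= 65")
  bad <- ok; bad$home_care_min[1] <- -5
  expect_error(validate_cohort(bad), "home_care_min must be missing or >= 0")
  bad <- ok; bad$wave[2] <- "baseline"
  expect_error(validate_cohort(bad), "duplicate record .* 'c01' .* 'baseline'")
  bad <- ok; bad$status[2] <- "teleported"
  expect_error(validate_cohort(bad), "status must be one of")
})

test_that("blank quantities load as missing, never as zero", {
  co <- two_wave_cohort(2, informal_min = 30)
  co$informal_min[2] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- load_cohort(f)
  expect_true(is.na(back$informal_min[2]))
  expect_identical(back$informal_min[1], 30)
})

cohort_columns_for_test <- function() {
  c("client_id", "org_id", "country", "wave", "age", "sex",
    "living_alone", "cps", "drs", "adlh", "iadl", "chess",
    "caregiver_distress", "status", "facility", "hosp_events",
    "hosp_days", "er_visits", "phys_visits", "home_care_min",
    "therapist_min", "supportive_units", "other_hc_units",
    "informal_min")
}

test_that("write/load round trip is bit-exact for numerics and labels", {
  sc <- quick_scenario(n_per_org = 15, missing_rate = 0.1, seed = 3,
                       transition_probs = c(deceased = 0.1,
                                            institutionalized = 0.1,
                                            discharged = 0.05,
                                            lost = 0.05))
  co <- generate_cohort(sc)$cohort
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- load_cohort(f)
  co_plain <- as.data.frame(co)[cohort_columns_for_test()]
  back_plain <- as.data.frame(back)[cohort_columns_for_test()]
  for (cl in names(co_plain))
    expect_identical(back_plain[[cl]], co_plain[[cl]], label = cl)
})

test_that("price tables are validated for completeness and sign", {
  uc <- c(hospital_night = 100, er_visit = 50, physician_visit = 10,
          home_care_hour = 30, therapist_hour = 20, supportive_unit = 5,
          other_healthcare_unit = 8)
  los <- c(NL = 8, IT = 7, IS = 6, FI = 7, GE = 7.5)
  expect_error(
    price_table("t", uc, informal_care_wage = NULL,
                facility_per_diem = c(nursing_home = 150),
                hospital_los = los),
    "informal_care_wage")
  expect_error(
    price_table("t", uc[-1], informal_care_wage = 12,
                facility_per_diem = c(nursing_home = 150),
                hospital_los = los),
    "hospital_night")
  expect_error(
    price_table("t", uc, informal_care_wage = 12,
                facility_per_diem = c(nursing_home = -1),
                hospital_los = los),
    "negative")
  expect_error(
    price_table("t", uc, informal_care_wage = 12,
                facility_per_diem = c(nursing_home = 150),
                hospital_los = los[-1]),
    "length-of-stay for: NL")
})

test_that("several named price tables coexist and are retrievable", {
  tabs <- carecost_prices()
  expect_named(tabs, c("dutch_reference", "italian_alternate"))
  expect_s3_class(tabs$italian_alternate, "price_table")
  one <- carecost_prices("italian_alternate")
  expect_identical(one$name, "italian_alternate")
  expect_error(carecost_prices("nope"), "no price table named")
})

test_that("run configuration validates its invariants and loads from YAML", {
  expect_error(carecost_config(alpha = 0), "alpha")
  expect_error(carecost_config(alpha = 1), "alpha")
  expect_error(carecost_config(interpolation_weights = c(0.5, 1)),
               "sum")
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(perspective = "healthcare", n_bootstrap = 100,
                        rng_seed = 9), f)
  cfg <- load_config(f)
  expect_identical(cfg$perspective, "healthcare")
  expect_identical(cfg$n_bootstrap, 100L)
  expect_identical(cfg$n_imputations, 10L)   # default preserved
  yaml::write_yaml(list(bogus_key = 1), f)
  expect_error(load_config(f), "unknown configuration keys: bogus_key")
})
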