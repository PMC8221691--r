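# Independent oracles and fixture builders.  Each oracle re-derives its
# quantity from first principles (enumeration, day-by-day accrual,
# normal equations) without touching the implementation it checks.

# --- BCa oracle: formula-by-formula, with its own quantile interpolation.
oracle_bca <- function(t0, t, t_jack, alpha = 0.05) {
  B <- length(t)
  p <- (sum(t < t0) + 0.5 * sum(t == t0)) / B
  z0 <- qnorm(p)
  tm <- mean(t_jack)
  num <- sum((tm - t_jack)^3)
  den <- 6 * (sum((tm - t_jack)^2))^1.5
  a <- if (den == 0) 0 else num / den
  s <- sort(t)
  vapply(c(alpha / 2, 1 - alpha / 2), function(al) {
    z <- qnorm(al)
    pp <- pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
    h <- (B - 1) * pp + 1           # linear interpolation of order stats
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, B)] - s[lo])
  }, numeric(1))
}

# Exhaustive resample statistics for a sample of size n: all n^n index
# vectors, decoded base-n (independent of expand.grid).
oracle_enumerate_stats <- function(x, statistic) {
  n <- length(x)
  vapply(0:(n^n - 1), function(code) {
    idx <- integer(n)
    for (j in seq_len(n)) {
      idx[j] <- code %% n + 1
      code <- code %/% n
    }
    statistic(x[idx])
  }, numeric(1))
}

# --- Day-by-day accrual over the 182-day window.
# q1, q2: named per-category quarterly costs; q2 is the *observed*
# month-6 assessment (used only while in care).  Community categories
# accrue at the average of the two assessed rates in the first quarter
# and the month-6 rate in the second while in care; after a mid-window
# death or institutionalization the baseline community rate applies up
# to day 91 and zero / the facility per-diem afterwards.
oracle_day_accrual <- function(q1, q2, status, per_diem = 0, Q = 91) {
  cats <- names(q1)
  total <- setNames(numeric(length(cats)), cats)
  for (ct in cats) {
    for (day in seq_len(2 * Q)) {
      pre <- day <= Q
      rate <-
        if (status == "in_care") {
          if (pre) (q1[[ct]] + q2[[ct]]) / (2 * Q) else q2[[ct]] / Q
        } else if (status == "deceased") {
          if (pre) q1[[ct]] / Q else 0
        } else if (status == "institutionalized") {
          if (ct == "institutional") {
            if (pre) q1[[ct]] / Q else per_diem
          } else {
            if (pre) q1[[ct]] / Q else 0
          }
        } else NA_real_
      total[[ct]] <- total[[ct]] + rate
    }
  }
  total
}

# --- OLS by explicit normal equations.
oracle_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X) %*% (t(X) %*% y))
}

# --- Fixture builders -------------------------------------------------

test_prices <- function() {
  price_table("test",
    unit_costs = c(hospital_night = 100, er_visit = 50,
                   physician_visit = 10, home_care_hour = 30,
                   therapist_hour = 20, supportive_unit = 5,
                   other_healthcare_unit = 8),
    informal_care_wage = 12,
    facility_per_diem = c(nursing_home = 150, rehabilitation = 300),
    hospital_los = c(NL = 8, IT = 7, IS = 6, FI = 7, GE = 7.5))
}

cohort_row <- function(client_id = "c1", org_id = "o1", country = "NL",
                       wave = "baseline", age = 80, sex = "female",
                       living_alone = TRUE, cps = 1, drs = 1, adlh = 1,
                       iadl = 10, chess = 1, caregiver_distress = FALSE,
                       status = "in_care", facility = NA_character_,
                       hosp_events = 0, hosp_days = NA_real_,
                       er_visits = 0, phys_visits = 0,
                       home_care_min = 0, therapist_min = 0,
                       supportive_units = 0, other_hc_units = 0,
                       informal_min = 0) {
  data.frame(client_id = client_id, org_id = org_id, country = country,
             wave = wave, age = age, sex = sex,
             living_alone = living_alone, cps = cps, drs = drs,
             adlh = adlh, iadl = iadl, chess = chess,
             caregiver_distress = caregiver_distress, status = status,
             facility = facility, hosp_events = hosp_events,
             hosp_days = hosp_days, er_visits = er_visits,
             phys_visits = phys_visits, home_care_min = home_care_min,
             therapist_min = therapist_min,
             supportive_units = supportive_units,
             other_hc_units = other_hc_units,
             informal_min = informal_min, stringsAsFactors = FALSE)
}

# Two-wave cohort for k clients, all quantities zero unless overridden.
two_wave_cohort <- function(k = 3, ...) {
  rows <- lapply(seq_len(k), function(i) {
    rbind(cohort_row(client_id = sprintf("c%02d", i), wave = "baseline",
                     ...),
          cohort_row(client_id = sprintf("c%02d", i), wave = "month6",
                     ...))
  })
  do.call(rbind, rows)
}

# Small generator scenario (transition-free, no missingness by default).
quick_scenario <- function(models = c("CM1", "CM2"), n_per_org = 40,
                           effects = NULL, missing_rate = 0,
                           transition_probs = c(deceased = 0,
                                                institutionalized = 0,
                                                discharged = 0,
                                                lost = 0),
                           seed = 1, ...) {
  if (is.null(effects))
    effects <- setNames(rep(0, length(models)), models)
  simulation_scenario(
    n_orgs_per_model = setNames(rep(1L, length(models)), models),
    n_clients_per_org = setNames(rep(n_per_org, length(models)), models),
    countries_by_model = setNames(
      list("NL", "FI", "GE")[seq_along(models)], models),
    true_model_effects = effects,
    transition_probs = transition_probs,
    missingness = list(mechanism = "MCAR", rate = missing_rate),
    seed = seed, ...)
}
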