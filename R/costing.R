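# Costing engine: convert per-wave resource utilization into quarterly
# and 6-month per-client costs in seven categories.
#
# Semantics fixed here and pinned by the day-by-day accrual oracle in the
# test suite:
#  * quantities are scaled to a quarter as quantity * quarter_days /
#    recall_days (no premature rounding anywhere; money is full precision
#    internally and reported to the cent in tables);
#  * hospital nights are admission counts times the country mean length
#    of stay, except in the recorded-days country where the registered
#    total number of admission days is used directly;
#  * the 6-month total interpolates the two quarterly assessments with
#    weights 0.5 (baseline) and 1.5 (month 6), i.e. the first quarter
#    accrues the average of the two assessed rates and the second quarter
#    the month-6 rate;
#  * for clients who died or were institutionalized between assessments
#    the event is placed halfway through the 182-day window: the first
#    91 days accrue community costs at the baseline rate, the remaining
#    91 days accrue zero (death) or the facility per-diem
#    (institutionalization).  apply_transition_rules() returns the
#    *effective* month-6 quarterly costs implied by that schedule, so the
#    0.5/1.5 interpolation identity holds exactly for every client;
#  * clients discharged or lost to follow-up have missing month-6 costs
#    (imputation's job), not extrapolated ones.

#' Scale a recall-period quantity to a quarter
#'
#' Resource-use quantities are reported over item-specific recall periods
#' (90 days for hospitalization, emergency-room and physician visits, 7
#' days for home care and therapists, 3 days for informal care) and are
#' scaled to a common quarter: `quantity * quarter_days / recall_days`.
#'
#' @param quantity Non-negative count or minutes; `NA` propagates.
#' @param recall_days Recall period in days (90, 7 or 3).
#' @param quarter_days Days per quarter (default 91).
#' @return Quantity per quarter.
#' @export
scale_to_quarter <- function(quantity, recall_days, quarter_days = 91) {
  if (any(!is.na(quantity) & quantity < 0))
    stop("quantity must be missing or >= 0", call. = FALSE)
  quantity * quarter_days / recall_days
}

#' Estimate hospital nights from admission counts
#'
#' The assessment instrument records the number of hospital stays, not
#' nights; nights are estimated as events times the country-specific mean
#' length of stay.  In the recorded-days country the registered total
#' number of admission days is used directly instead.
#'
#' @param events Number of admissions in the recall period.
#' @param country Country code per client.
#' @param recorded_days Registered admission days (used only for the
#'   recorded-days country).
#' @param prices A [price_table()] supplying `hospital_los` and the
#'   recorded-days country.
#' @return Nights in the recall period (vectorized).
#' @export
hospital_nights <- function(events, country, recorded_days = NULL,
                            prices) {
  stopifnot(inherits(prices, "price_table"))
  n <- max(length(events), length(country))
  events <- rep_len(events, n)
  country <- rep_len(country, n)
  recorded_days <- if (is.null(recorded_days)) rep(NA_real_, n)
                   else rep_len(recorded_days, n)
  if (any(!is.na(events) & events < 0))
    stop("events must be missing or >= 0", call. = FALSE)
  rec <- country == prices$recorded_days_country
  need_los <- unique(country[!rec])
  no_los <- setdiff(need_los, names(prices$hospital_los))
  if (length(no_los))
    stop("no hospital length-of-stay entry for: ",
         paste(no_los, collapse = ", "), call. = FALSE)
  nights <- numeric(n)
  nights[rec] <- recorded_days[rec]
  nights[!rec] <- events[!rec] *
    unname(prices$hospital_los[country[!rec]])
  nights
}

#' Value one assessment wave into quarterly category costs
#'
#' Multiplies each client's scaled resource quantities by the standard
#' unit costs and accumulates them into the seven cost categories.
#' Emergency-room and physician visits are pooled into one visit
#' category; therapist minutes are costed within the home-care category
#' (shared 7-day recall); minute items are converted to hours before the
#' hourly price or (for informal care) the proxy-good wage rate is
#' applied.  Institutional care never accrues at an assessment wave
#' (clients are community-dwelling when assessed); it enters only through
#' the transition rules.  A missing quantity makes its category cost
#' missing for that client (to be imputed), it is never treated as zero.
#'
#' @param wave_data Cohort rows of a single wave.
#' @param prices A [price_table()].
#' @param config A [carecost_config()].
#' @return Numeric matrix, one row per row of `wave_data`, one column per
#'   category of [cost_categories()]: quarterly costs.
#' @export
value_wave <- function(wave_data, prices, config = carecost_config()) {
  stopifnot(inherits(prices, "price_table"))
  n <- nrow(wave_data)
  Q <- config$quarter_days
  cats <- cost_categories()
  out <- matrix(0, n, length(cats), dimnames = list(NULL, cats))

  uc <- prices$unit_costs
  nights <- hospital_nights(wave_data$hosp_events, wave_data$country,
                            wave_data$hosp_days, prices)
  out[, "hospital"] <- scale_to_quarter(nights, 90, Q) *
    uc[["hospital_night"]]
  out[, "visits"] <-
    scale_to_quarter(wave_data$er_visits, 90, Q) * uc[["er_visit"]] +
    scale_to_quarter(wave_data$phys_visits, 90, Q) * uc[["physician_visit"]]
  out[, "home_care"] <-
    scale_to_quarter(wave_data$home_care_min / 60, 7, Q) *
      uc[["home_care_hour"]] +
    scale_to_quarter(wave_data$therapist_min / 60, 7, Q) *
      uc[["therapist_hour"]]
  out[, "supportive"] <-
    scale_to_quarter(wave_data$supportive_units, 90, Q) *
    uc[["supportive_unit"]]
  out[, "other_healthcare"] <-
    scale_to_quarter(wave_data$other_hc_units, 90, Q) *
    uc[["other_healthcare_unit"]]
  out[, "informal"] <-
    scale_to_quarter(wave_data$informal_min / 60, 3, Q) *
    prices$informal_care_wage
  out[, "institutional"] <- 0
  out
}

#' Apply the halfway transition rules to month-6 quarterly costs
#'
#' For clients still in care the observed month-6 costs pass through
#' unchanged.  For clients who died or were admitted to another care
#' setting, the event is assumed to have occurred halfway between the two
#' assessments: community costs accrue at the baseline rate for the first
#' 91 days of the 182-day window, and after the event costs are zero
#' (death) or the facility's standard per-diem (institutionalization).
#' The returned matrix holds the effective month-6 quarterly costs
#' implied by that schedule, chosen so that
#' `w1 * baseline + w2 * effective` reproduces the day-by-day accrual
#' total exactly.  Discharged and lost clients get missing month-6 costs.
#'
#' @param q1 Baseline quarterly category costs (matrix from
#'   [value_wave()]).
#' @param q2 Observed month-6 quarterly category costs.
#' @param status Month-6 status per client: `in_care`,
#'   `institutionalized`, `deceased`, `discharged`, `lost`.
#' @param facility Facility per-diem key per client (required for the
#'   institutionalized).
#' @param prices A [price_table()] supplying `facility_per_diem`.
#' @param config A [carecost_config()].
#' @return Matrix of effective month-6 quarterly category costs.
#' @export
apply_transition_rules <- function(q1, q2, status, facility = NULL,
                                   prices, config = carecost_config()) {
  stopifnot(nrow(q1) == nrow(q2), nrow(q1) == length(status))
  w <- config$interpolation_weights
  Q <- config$quarter_days
  out <- q2
  ended <- status %in% c("deceased", "institutionalized")
  if (any(ended)) {
    # community categories: accrual target over the window is one
    # baseline quarter (community rate until the midpoint, then none)
    out[ended, ] <- q1[ended, , drop = FALSE] * (1 - w[1]) / w[2]
  }
  inst <- status == "institutionalized"
  if (any(inst)) {
    if (is.null(facility))
      stop("institutionalized clients need a facility per-diem key",
           call. = FALSE)
    fac <- facility[inst]
    if (any(is.na(fac)) || !all(fac %in% names(prices$facility_per_diem)))
      stop("no facility per-diem for: ",
           paste(unique(fac[is.na(fac) |
             !fac %in% names(prices$facility_per_diem)]), collapse = ", "),
           call. = FALSE)
    per_diem <- unname(prices$facility_per_diem[fac])
    # per-diem accrues for the 91 post-midpoint days of the window
    out[inst, "institutional"] <-
      (Q * per_diem - w[1] * q1[inst, "institutional"]) / w[2]
  }
  gone <- status %in% c("discharged", "lost")
  if (any(gone)) out[gone, ] <- NA_real_
  out
}

#' Six-month cost by linear interpolation of the two assessments
#'
#' `w1 * baseline_quarter + w2 * month6_quarter` with default weights
#' 0.5 and 1.5: the first three months are costed at the average of the
#' two assessed rates, the second three months at the month-6 rate.
#'
#' @param cost_baseline_quarter Baseline quarterly cost(s).
#' @param cost_month6_quarter Month-6 quarterly cost(s).
#' @param weights Length-2 interpolation weights summing to 2.
#' @return Six-month cost(s).
#' @export
six_month_cost <- function(cost_baseline_quarter, cost_month6_quarter,
                           weights = c(0.5, 1.5)) {
  stopifnot(length(weights) == 2)
  weights[1] * cost_baseline_quarter + weights[2] * cost_month6_quarter
}

#' Per-client six-month cost breakdown
#'
#' Runs the full costing engine over a cohort: values both assessment
#' waves, applies the halfway transition rules to the month-6 quarter,
#' and interpolates to 6-month costs in the seven categories plus the
#' societal total (sum of all categories) and the healthcare total
#' (societal minus informal care).  Missing resource quantities propagate
#' to missing category costs; they are the imputation stage's input, and
#' totals are only defined once all categories are observed or imputed.
#'
#' @param cohort A validated cohort (see [load_cohort()]).
#' @param prices A [price_table()].
#' @param config A [carecost_config()].
#' @return Data frame of class `"cost_breakdown"`: one row per client
#'   with identifiers, case-mix covariates, month-6 status, quarterly
#'   category costs `q1_*` and `q2_*` (effective, post-transition),
#'   6-month category costs `c6m_*`, `total_societal_6m` and
#'   `total_healthcare_6m`.
#' @export
client_costs <- function(cohort, prices, config = carecost_config()) {
  cohort <- validate_cohort(cohort, config)
  base <- cohort[cohort$wave == "baseline", , drop = FALSE]
  fup <- cohort[cohort$wave == "month6", , drop = FALSE]
  if (!nrow(base))
    stop("cohort has no baseline records", call. = FALSE)
  fup <- fup[match(base$client_id, fup$client_id), , drop = FALSE]

  status <- fup$status
  status[is.na(status)] <- "lost"   # no month-6 record at all
  facility <- fup$facility

  q1 <- value_wave(base, prices, config)
  q2_obs <- matrix(NA_real_, nrow(base), length(cost_categories()),
                   dimnames = list(NULL, cost_categories()))
  has_fup <- !is.na(fup$client_id)
  if (any(has_fup))
    q2_obs[has_fup, ] <- value_wave(fup[has_fup, , drop = FALSE],
                                    prices, config)
  q2 <- apply_transition_rules(q1, q2_obs, status, facility, prices,
                               config)
  c6m <- six_month_cost(q1, q2, config$interpolation_weights)

  cats <- cost_categories()
  out <- data.frame(client_id = base$client_id, org_id = base$org_id,
                    country = base$country, status = status,
                    base[casemix_vars()],
                    caregiver_distress = base$caregiver_distress,
                    stringsAsFactors = FALSE)
  colnames(q1) <- paste0("q1_", cats)
  colnames(q2) <- paste0("q2_", cats)
  colnames(c6m) <- paste0("c6m_", cats)
  out <- cbind(out, q1, q2, c6m)
  out$total_societal_6m <- rowSums(c6m)
  out$total_healthcare_6m <- out$total_societal_6m - c6m[, "c6m_informal"]
  rownames(out) <- NULL
  class(out) <- c("cost_breakdown", class(out))
  attr(out, "manifest") <- list(price_table = prices$name,
                                quarter_days = config$quarter_days,
                                weights = config$interpolation_weights)
  out
}

# Recompute the 6-month category costs and totals from the q1_/q2_
# columns (used after imputation so the interpolation identity holds in
# every completed dataset).
recompute_totals <- function(breakdown, weights = c(0.5, 1.5)) {
  cats <- cost_categories()
  for (ct in cats) {
    breakdown[[paste0("c6m_", ct)]] <-
      six_month_cost(breakdown[[paste0("q1_", ct)]],
                     breakdown[[paste0("q2_", ct)]], weights)
  }
  c6m <- as.matrix(breakdown[paste0("c6m_", cats)])
  breakdown$total_societal_6m <- rowSums(c6m)
  breakdown$total_healthcare_6m <-
    breakdown$total_societal_6m - breakdown$c6m_informal
  breakdown
}

#' Aggregate cost breakdowns by care model
#'
#' Per-model mean disaggregated 6-month costs with standard errors,
#' category shares of the total, and the informal-to-home-care cost
#' ratio.  Under the healthcare perspective the informal-care category is
#' excluded from totals and shares.  Groups with no complete breakdowns
#' are flagged and excluded.
#'
#' @param breakdown A `"cost_breakdown"` data frame (complete, i.e. after
#'   imputation, for exact group means; rows with missing totals are
#'   dropped with a message).
#' @param assignments A `"care_model_assignment"` table (or any data
#'   frame with `org_id` and `model`); alternatively `breakdown` may
#'   already contain a `model` column.
#' @param perspective `"societal"` or `"healthcare"`.
#' @return Data frame of class `"cost_aggregate"`: one row per care
#'   model with `n`, mean cost per category, `total_mean`, `total_se`,
#'   `share_*` percentages and `informal_home_ratio`.
#' @export
aggregate_costs <- function(breakdown, assignments = NULL,
                            perspective = c("societal", "healthcare")) {
  perspective <- match.arg(perspective)
  if (!is.null(assignments)) {
    breakdown$model <-
      assignments$model[match(breakdown$org_id, assignments$org_id)]
  }
  if (is.null(breakdown$model))
    stop("no care-model assignment for the breakdowns", call. = FALSE)
  cats <- cost_categories()
  use_cats <- if (perspective == "healthcare")
    setdiff(cats, "informal") else cats
  total_col <- if (perspective == "healthcare")
    "total_healthcare_6m" else "total_societal_6m"

  ok <- stats::complete.cases(breakdown[paste0("c6m_", cats)])
  if (any(!ok))
    message(sum(!ok), " clients with incomplete costs dropped from the ",
            "aggregate (impute first for full-cohort means)")
  bd <- breakdown[ok, , drop = FALSE]

  models <- sort(unique(breakdown$model))
  rows <- lapply(models, function(mdl) {
    g <- bd[bd$model == mdl, , drop = FALSE]
    if (!nrow(g)) {
      warning("care model ", mdl,
              " has no complete breakdowns; excluded", call. = FALSE)
      return(NULL)
    }
    means <- vapply(use_cats, function(ct)
      mean(g[[paste0("c6m_", ct)]]), numeric(1))
    tot <- g[[total_col]]
    row <- data.frame(model = mdl, n = nrow(g),
                      total_mean = mean(tot),
                      total_se = stats::sd(tot) / sqrt(nrow(g)))
    for (ct in use_cats) row[[paste0("mean_", ct)]] <- means[[ct]]
    for (ct in use_cats)
      row[[paste0("share_", ct)]] <- 100 * means[[ct]] / sum(means)
    hc <- mean(g$c6m_home_care)
    row$informal_home_ratio <-
      if (perspective == "healthcare" || hc == 0) NA_real_
      else mean(g$c6m_informal) / hc
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cost_aggregate", class(out))
  attr(out, "perspective") <- perspective
  out
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> %d clients (%d with complete 6-month costs)\n",
              nrow(x), sum(!is.na(x$total_societal_6m))))
  man <- attr(x, "manifest")
  if (!is.null(man))
    cat("  price table:", man$price_table, "| quarter:", man$quarter_days,
        "days | weights:", paste(man$weights, collapse = "/"), "\n")
  tot <- x$total_societal_6m
  if (any(!is.na(tot)))
    cat(sprintf("  mean societal 6-month cost (complete cases): %.2f\n",
                mean(tot, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.cost_aggregate <- function(x, ...) {
  cat("<cost_aggregate>", attr(x, "perspective"), "perspective\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 2)
  print(df)
  invisible(x)
}
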