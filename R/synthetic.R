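# Synthetic multi-country, multi-organization home-care cohorts with
# known ground truth.
#
# The generator emulates the statistical structure the benchmarking
# analysis assumes: right-skewed 6-month societal costs, case-mix
# confounding (utilization depends on ADL hierarchy and health
# instability), care-model-level shifts in expected adjusted cost,
# wave-2 attrition (death, institutionalization, discharge, loss to
# follow-up) and item-level missingness.  Skew is induced at the
# quantity level -- admission/visit counts are Poisson, care minutes are
# Gamma -- so the costing engine is exercised on realistic inputs and
# every expected value stays exactly linear in the scenario parameters.
# Default magnitudes mirror the European home-care study population the
# package targets (about 2000 clients in three care models, mean
# 6-month societal costs near EUR 16000-19000, an adjusted CM2-CM1
# difference of EUR 2230, 2% deaths and 3% institutionalizations over
# 6 months, and roughly 29% of clients with at least one missing
# utilization item).

dist_spec <- function(dist, ...) c(list(dist = dist), list(...))

default_case_mix <- function() {
  list(
    age = dist_spec("truncnorm", mean = 82.8, sd = 7.5, min = 65,
                    max = 105),
    sex = dist_spec("bernoulli", prob = 0.67),        # P(female)
    living_alone = dist_spec("bernoulli", prob = 0.59),
    cps = dist_spec("binomial", size = 6, prob = 0.27),
    drs = dist_spec("binomial", size = 14, prob = 0.08),
    adlh = dist_spec("binomial", size = 6, prob = 0.28),
    iadl = dist_spec("binomial", size = 48, prob = 0.61),
    chess = dist_spec("binomial", size = 5, prob = 0.20)
  )
}

default_case_mix_by_model <- function() {
  list(
    CM1 = list(living_alone = dist_spec("bernoulli", prob = 0.51),
               adlh = dist_spec("binomial", size = 6, prob = 0.317),
               chess = dist_spec("binomial", size = 5, prob = 0.24),
               iadl = dist_spec("binomial", size = 48, prob = 0.64)),
    CM2 = list(living_alone = dist_spec("bernoulli", prob = 0.73),
               cps = dist_spec("binomial", size = 6, prob = 0.15),
               adlh = dist_spec("binomial", size = 6, prob = 0.10),
               chess = dist_spec("binomial", size = 5, prob = 0.16),
               iadl = dist_spec("binomial", size = 48, prob = 0.48)),
    CM3 = list(living_alone = dist_spec("bernoulli", prob = 0.74),
               sex = dist_spec("bernoulli", prob = 0.71),
               cps = dist_spec("binomial", size = 6, prob = 0.31),
               adlh = dist_spec("binomial", size = 6, prob = 0.367),
               chess = dist_spec("binomial", size = 5, prob = 0.12),
               iadl = dist_spec("binomial", size = 48, prob = 0.61))
  )
}

default_category_shares <- function() {
  list(
    CM1 = c(hospital = 0.11, visits = 0.04, other_healthcare = 0.02,
            supportive = 0.03, institutional = 0, home_care = 0.20,
            informal = 0.60),
    CM2 = c(hospital = 0.12, visits = 0.10, other_healthcare = 0.08,
            supportive = 0.10, institutional = 0, home_care = 0.20,
            informal = 0.40),
    CM3 = c(hospital = 0.06, visits = 0.06, other_healthcare = 0.04,
            supportive = 0.05, institutional = 0, home_care = 0.54,
            informal = 0.25)
  )
}

dist_mean <- function(d) {
  switch(d$dist,
    truncnorm = {
      a <- (d$min - d$mean) / d$sd
      b <- (d$max - d$mean) / d$sd
      d$mean + d$sd * (stats::dnorm(a) - stats::dnorm(b)) /
        (stats::pnorm(b) - stats::pnorm(a))
    },
    binomial = d$size * d$prob,
    bernoulli = d$prob,
    stop("unknown distribution '", d$dist, "'", call. = FALSE))
}

dist_draw <- function(d, n) {
  switch(d$dist,
    truncnorm = {
      out <- numeric(0)
      while (length(out) < n) {
        x <- stats::rnorm(n, d$mean, d$sd)
        out <- c(out, x[x >= d$min & x <= d$max])
      }
      out[seq_len(n)]
    },
    binomial = stats::rbinom(n, d$size, d$prob),
    bernoulli = stats::rbinom(n, 1, d$prob),
    stop("unknown distribution '", d$dist, "'", call. = FALSE))
}

#' Define a simulation scenario
#'
#' Collects every knob of the synthetic-cohort generator: design
#' (organizations per model, clients per organization, country pools),
#' the injected care-model effects on expected 6-month societal cost,
#' the case-mix distributions (shared plus per-model overrides, which
#' create the confounding the adjusted analysis must remove), the
#' coefficients linking case-mix scores to expected cost, the per-model
#' split of expected cost over the seven categories, the right-skew
#' shape of the quantity draws, 6-month transition probabilities and the
#' item-missingness mechanism.
#'
#' @param n_orgs_per_model Named integer: organizations per care model.
#' @param n_clients_per_org Clients per organization; a single count or
#'   a named vector by model.
#' @param countries_by_model Named list: country pool per model
#'   (organizations cycle through their model's pool).
#' @param base_cost Expected 6-month societal cost (money) of a client
#'   with all case-mix scores zero in the reference model.
#' @param true_model_effects Named numeric: additive shift in expected
#'   6-month societal cost per model.  These are the adjusted
#'   differences the inference stage should recover.
#' @param confounding_strength Named numeric: money per point of each
#'   case-mix score added to the expected cost (default: ADLH and CHESS
#'   only).
#' @param case_mix Named list of distribution specs (see defaults).
#' @param case_mix_by_model Per-model overrides of `case_mix`.
#' @param category_shares Named list: per-model share of expected cost
#'   in each category (each must sum to 1; institutional share must be
#'   0 -- institutional costs arise only from transitions).
#' @param gamma_shape Shape of the Gamma draws for minute quantities
#'   (smaller = more right-skewed).
#' @param transition_probs Named probabilities of `deceased`,
#'   `institutionalized`, `discharged`, `lost` by month 6 (sum <= 1;
#'   remainder stays in care).
#' @param facility Facility per-diem key for institutionalized clients.
#' @param missingness List with `mechanism` ("MCAR" or "MAR"), `rate`
#'   in `[0, 1]`, optionally `waves` and `mar_coef` (see
#'   [inject_missingness()]).
#' @param seed Integer seed; identical scenarios and seeds give
#'   byte-identical cohorts.
#' @return A list of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(n_orgs_per_model = c(CM1 = 6, CM2 = 3,
                                                     CM3 = 9),
                                n_clients_per_org = c(CM1 = 222,
                                                      CM2 = 104,
                                                      CM3 = 46),
                                countries_by_model =
                                  list(CM1 = c("IT", "NL", "IS", "FI"),
                                       CM2 = c("NL", "FI"),
                                       CM3 = "GE"),
                                base_cost = 11000,
                                true_model_effects = c(CM1 = 0,
                                                       CM2 = 2230,
                                                       CM3 = -322),
                                confounding_strength = c(adlh = 3200,
                                                         chess = 1500),
                                case_mix = default_case_mix(),
                                case_mix_by_model =
                                  default_case_mix_by_model(),
                                category_shares =
                                  default_category_shares(),
                                gamma_shape = 0.8,
                                transition_probs =
                                  c(deceased = 0.02,
                                    institutionalized = 0.03,
                                    discharged = 0.007, lost = 0.026),
                                facility = "nursing_home",
                                missingness = list(mechanism = "MCAR",
                                                   rate = 0.02),
                                seed = 1L) {
  models <- names(n_orgs_per_model)
  if (is.null(models) || !length(models))
    stop("n_orgs_per_model must be a named vector of care models",
         call. = FALSE)
  if (length(n_clients_per_org) == 1 && is.null(names(n_clients_per_org)))
    n_clients_per_org <- stats::setNames(rep(n_clients_per_org,
                                             length(models)), models)
  stopifnot(all(models %in% names(n_clients_per_org)),
            all(models %in% names(countries_by_model)),
            all(models %in% names(true_model_effects)),
            gamma_shape > 0)
  tp <- transition_probs
  if (any(tp < 0) || any(tp > 1) || sum(tp) > 1)
    stop("transition probabilities must lie in [0,1] and sum to <= 1",
         call. = FALSE)
  if (is.null(missingness$rate)) missingness$rate <- 0
  if (missingness$rate < 0 || missingness$rate > 1)
    stop("missingness rate must lie in [0,1]", call. = FALSE)
  shares <- if (!is.null(names(category_shares)) &&
                !is.numeric(category_shares)) category_shares
            else stats::setNames(rep(list(category_shares), length(models)),
                                 models)
  for (mdl in models) {
    sh <- shares[[mdl]]
    if (is.null(sh)) stop("no category shares for ", mdl, call. = FALSE)
    if (length(setdiff(cost_categories(), names(sh))))
      stop("category shares for ", mdl, " must name all of: ",
           paste(cost_categories(), collapse = ", "), call. = FALSE)
    if (any(sh < 0) || abs(sum(sh) - 1) > 1e-8)
      stop("category shares for ", mdl,
           " must be non-negative and sum to 1", call. = FALSE)
    if (sh[["institutional"]] != 0)
      stop("institutional share must be 0 (institutional costs arise ",
           "only from transitions)", call. = FALSE)
  }
  # feasibility: the lowest attainable expected cost must be positive
  worst <- min(true_model_effects[models]) + base_cost
  for (v in names(confounding_strength)) {
    if (confounding_strength[[v]] < 0) {
      d <- case_mix[[v]]
      vmax <- switch(d$dist, binomial = d$size, bernoulli = 1,
                     truncnorm = d$max)
      worst <- worst + confounding_strength[[v]] * vmax
    }
  }
  if (worst <= 0)
    stop("infeasible scenario: expected cost can be non-positive",
         call. = FALSE)

  structure(list(models = models,
                 n_orgs_per_model = n_orgs_per_model,
                 n_clients_per_org = n_clients_per_org,
                 countries_by_model = countries_by_model,
                 base_cost = base_cost,
                 true_model_effects = true_model_effects,
                 confounding_strength = confounding_strength,
                 case_mix = case_mix,
                 case_mix_by_model = case_mix_by_model,
                 category_shares = shares,
                 gamma_shape = gamma_shape,
                 transition_probs = tp,
                 facility = facility,
                 missingness = missingness,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

# Per-model case-mix spec with overrides applied.
model_case_mix <- function(scenario, mdl) {
  cm <- scenario$case_mix
  ov <- scenario$case_mix_by_model[[mdl]]
  if (!is.null(ov)) cm[names(ov)] <- ov
  cm
}

#' Scenario-implied expected 6-month societal cost per care model
#'
#' For transition-free scenarios, the expected complete-data 6-month
#' societal cost of a client in model `g` is
#' `base_cost + effect[g] + sum_k beta_k E[score_k | g]`, with the
#' case-mix expectations taken analytically from the scenario's
#' distributions.  (With transitions, deaths accrue half and
#' institutionalizations half plus a facility quarter; see the costing
#' engine.  The identity reported here is the transition-free one the
#' marginal-control check uses.)
#'
#' @param scenario A [simulation_scenario()].
#' @return Named numeric: expected cost per model.
#' @export
expected_model_costs <- function(scenario) {
  vapply(scenario$models, function(mdl) {
    cm <- model_case_mix(scenario, mdl)
    contrib <- sum(vapply(names(scenario$confounding_strength),
      function(v) scenario$confounding_strength[[v]] * dist_mean(cm[[v]]),
      numeric(1)))
    scenario$base_cost + scenario$true_model_effects[[mdl]] + contrib
  }, numeric(1))
}

# Draw resource-use quantities for one wave, given per-client expected
# quarterly category costs (matrix n x 7), countries and prices.
draw_wave_items <- function(mu_q, country, prices, scenario, config) {
  n <- nrow(mu_q)
  Q <- config$quarter_days
  uc <- prices$unit_costs
  shape <- scenario$gamma_shape
  rgam <- function(mu) {
    out <- numeric(length(mu))
    pos <- mu > 0
    out[pos] <- stats::rgamma(sum(pos), shape = shape,
                              scale = mu[pos] / shape)
    out
  }
  rpois_mu <- function(mu) stats::rpois(n, mu)

  # hospital: expected nights per quarter -> admissions (or recorded
  # days in the recorded-days country) over the 90-day recall
  nights_q <- mu_q[, "hospital"] / uc[["hospital_night"]]
  rec <- country == prices$recorded_days_country
  los <- rep(7, n)
  los[!rec] <- unname(prices$hospital_los[country[!rec]])
  ev_mu <- nights_q / los * 90 / Q
  hosp_events <- rpois_mu(ev_mu)
  hosp_days <- rep(NA_real_, n)
  if (any(rec))
    hosp_days[rec] <- stats::rpois(sum(rec),
                                   (nights_q * 90 / Q)[rec])

  er_mu <- 0.4 * mu_q[, "visits"] / uc[["er_visit"]] * 90 / Q
  ph_mu <- 0.6 * mu_q[, "visits"] / uc[["physician_visit"]] * 90 / Q
  hc_mu <- 0.85 * mu_q[, "home_care"] / uc[["home_care_hour"]] *
    7 / Q * 60
  th_mu <- 0.15 * mu_q[, "home_care"] / uc[["therapist_hour"]] *
    7 / Q * 60
  su_mu <- mu_q[, "supportive"] / uc[["supportive_unit"]] * 90 / Q
  oh_mu <- mu_q[, "other_healthcare"] /
    uc[["other_healthcare_unit"]] * 90 / Q
  inf_mu <- mu_q[, "informal"] / prices$informal_care_wage * 3 / Q * 60

  data.frame(hosp_events = as.numeric(hosp_events),
             hosp_days = hosp_days,
             er_visits = as.numeric(rpois_mu(er_mu)),
             phys_visits = as.numeric(rpois_mu(ph_mu)),
             home_care_min = rgam(hc_mu),
             therapist_min = rgam(th_mu),
             supportive_units = as.numeric(rpois_mu(su_mu)),
             other_hc_units = as.numeric(rpois_mu(oh_mu)),
             informal_min = rgam(inf_mu))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces a two-wave cohort table that always passes
#' [validate_cohort()], an organization questionnaire table whose item
#' scores classify each organization into its intended care model, and a
#' ground-truth record of every injected effect.  For each client, the
#' expected valued 6-month societal cost equals
#' `base_cost + effect[model] + sum_k beta_k score_k` exactly (Poisson /
#' Gamma quantity draws are mean-calibrated through the price table);
#' wave-2 transitions replace the month-6 assessment with a status
#' record, and item missingness is injected by the scenario's mechanism.
#' Identical scenario and seed give identical output.
#'
#' @param scenario A [simulation_scenario()].
#' @param prices A [price_table()] used to back out quantities from
#'   target costs (use the same table downstream for exact recovery).
#' @param config A [carecost_config()].
#' @return List with `cohort` (validated `"carecost_cohort"`),
#'   `organizations` (questionnaire table), and `truth` (list: per-model
#'   expected costs, per-client expected costs, injected effects,
#'   confounding coefficients, seed).
#' @export
generate_cohort <- function(scenario,
                            prices = carecost_prices("dutch_reference"),
                            config = carecost_config()) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  models <- scenario$models
  patterns <- c(CM1 = "HHH", CM2 = "HLH", CM3 = "LLH", CM4 = "HHL",
                CM5 = "LHH", CM6 = "LLL")

  orgs <- list(); clients <- list()
  for (mdl in models) {
    n_org <- scenario$n_orgs_per_model[[mdl]]
    pool <- scenario$countries_by_model[[mdl]]
    pat <- strsplit(patterns[[mdl]], "")[[1]]
    for (o in seq_len(n_org)) {
      org_id <- sprintf("%s_org%02d", mdl, o)
      draw_items <- function(k, high)
        if (high) sample(3:4, k, replace = TRUE)
        else sample(0:1, k, replace = TRUE)
      it <- c(draw_items(6, pat[1] == "H"), draw_items(5, pat[2] == "H"),
              draw_items(4, pat[3] == "H"))
      org_row <- as.data.frame(as.list(stats::setNames(it,
                                                       org_item_columns())))
      org_row <- cbind(data.frame(org_id = org_id, model = mdl,
                                  country = pool[(o - 1) %% length(pool) + 1],
                                  stringsAsFactors = FALSE), org_row)
      orgs[[org_id]] <- org_row
      clients[[org_id]] <- scenario$n_clients_per_org[[mdl]]
    }
  }
  orgs <- do.call(rbind, orgs)
  rownames(orgs) <- NULL

  cm_rows <- list(); truth_mu <- list()
  for (oi in seq_len(nrow(orgs))) {
    org_id <- orgs$org_id[oi]
    mdl <- orgs$model[oi]
    n <- clients[[org_id]]
    cm <- model_case_mix(scenario, mdl)
    cli <- data.frame(
      client_id = sprintf("%s_c%04d", org_id, seq_len(n)),
      org_id = org_id, model = mdl, country = orgs$country[oi],
      age = round(dist_draw(cm$age, n), 1),
      sex = ifelse(dist_draw(cm$sex, n) == 1, "female", "male"),
      living_alone = dist_draw(cm$living_alone, n) == 1,
      cps = dist_draw(cm$cps, n), drs = dist_draw(cm$drs, n),
      adlh = dist_draw(cm$adlh, n), iadl = dist_draw(cm$iadl, n),
      chess = dist_draw(cm$chess, n),
      caregiver_distress = stats::rbinom(n, 1, 0.15) == 1,
      stringsAsFactors = FALSE)
    mu <- scenario$base_cost + scenario$true_model_effects[[mdl]]
    for (v in names(scenario$confounding_strength))
      mu <- mu + scenario$confounding_strength[[v]] * cli[[v]]
    if (any(mu <= 0))
      stop("infeasible scenario: non-positive expected cost generated",
           call. = FALSE)
    cli$mu <- mu
    cm_rows[[org_id]] <- cli
  }
  cli <- do.call(rbind, cm_rows)
  rownames(cli) <- NULL
  n_all <- nrow(cli)

  share_mat <- t(vapply(cli$model, function(mdl)
    scenario$category_shares[[mdl]][cost_categories()], numeric(7)))
  colnames(share_mat) <- cost_categories()
  mu_q <- share_mat * cli$mu / 2   # per-quarter expected category cost

  tp <- scenario$transition_probs
  status <- sample(c(names(tp), "in_care"), n_all, replace = TRUE,
                   prob = c(tp, 1 - sum(tp)))

  wave_frame <- function(wave, items, status, facility) {
    data.frame(client_id = cli$client_id, org_id = cli$org_id,
               country = cli$country, wave = wave, age = cli$age,
               sex = cli$sex, living_alone = cli$living_alone,
               cps = cli$cps, drs = cli$drs, adlh = cli$adlh,
               iadl = cli$iadl, chess = cli$chess,
               caregiver_distress = cli$caregiver_distress,
               status = status, facility = facility, items,
               stringsAsFactors = FALSE)
  }
  w1 <- wave_frame("baseline",
                   draw_wave_items(mu_q, cli$country, prices, scenario,
                                   config),
                   "in_care", NA_character_)
  items2 <- draw_wave_items(mu_q, cli$country, prices, scenario, config)
  gone <- status != "in_care"
  items2[gone, ] <- NA_real_
  facility2 <- ifelse(status == "institutionalized", scenario$facility,
                      NA_character_)
  w2 <- wave_frame("month6", items2, status, facility2)

  cohort <- rbind(w1, w2)
  cohort <- cohort[order(cohort$client_id, cohort$wave), ]
  rownames(cohort) <- NULL

  mis <- scenario$missingness
  if (mis$rate > 0) {
    cohort <- inject_missingness(
      cohort,
      mechanism = if (is.null(mis$mechanism)) "MCAR" else mis$mechanism,
      rate = mis$rate,
      mar_coef = if (is.null(mis$mar_coef)) 1 else mis$mar_coef,
      waves = if (is.null(mis$waves)) c("baseline", "month6")
              else mis$waves,
      unit = if (is.null(mis$unit)) "item" else mis$unit,
      seed = scenario$seed + 104729L)
  }
  cohort <- validate_cohort(cohort, config)

  truth <- list(base_cost = scenario$base_cost,
                true_model_effects = scenario$true_model_effects,
                confounding_strength = scenario$confounding_strength,
                expected_model_costs = expected_model_costs(scenario),
                expected_client_cost = stats::setNames(cli$mu,
                                                       cli$client_id),
                model_by_client = stats::setNames(cli$model,
                                                  cli$client_id),
                seed = scenario$seed)
  list(cohort = cohort, organizations = orgs[setdiff(names(orgs),
                                                     "model")],
       truth = truth)
}

#' Inject missingness into a cohort's resource-use quantities
#'
#' MCAR deletes each eligible unit independently with probability
#' `rate`.  MAR makes the deletion probability a logistic function of
#' the client's ADL hierarchy score:
#' `plogis(qlogis(rate) + mar_coef * (adlh - 3))`, so `rate` is the
#' rate at ADLH = 3 and positive coefficients concentrate missingness in
#' more dependent clients.  The unit is either a single item cell
#' (`unit = "item"`) or a client's whole assessment wave
#' (`unit = "wave"`, emulating a missed follow-up visit, i.e. missing
#' 6-month cost data).  Only observed cells are eligible (structurally
#' absent wave-2 quantities of clients who left care stay as they are).
#' Deterministic under `seed`.
#'
#' @param cohort A cohort table.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate Marginal deletion probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param mar_coef Logistic slope on `adlh - 3` (MAR only).
#' @param waves Waves whose items are eligible.
#' @param unit Delete independent item cells or whole wave rows.
#' @return The cohort with quantities deleted.
#' @export
inject_missingness <- function(cohort, mechanism = c("MCAR", "MAR"),
                               rate, seed = 1L, mar_coef = 1,
                               waves = c("baseline", "month6"),
                               unit = c("item", "wave")) {
  mechanism <- match.arg(mechanism)
  unit <- match.arg(unit)
  if (rate < 0 || rate > 1)
    stop("rate must lie in [0,1]", call. = FALSE)
  if (rate == 0) return(cohort)
  set.seed(seed)
  eligible_row <- cohort$wave %in% waves & cohort$status == "in_care"
  p_row <- if (mechanism == "MCAR") rep(rate, nrow(cohort))
           else stats::plogis(stats::qlogis(rate) +
                              mar_coef * (cohort$adlh - 3))
  if (unit == "wave") {
    del_row <- eligible_row & stats::runif(nrow(cohort)) < p_row
    for (it in carecost_items()$item_key)
      cohort[[it]][del_row] <- NA_real_
  } else {
    for (it in carecost_items()$item_key) {
      cell <- eligible_row & !is.na(cohort[[it]])
      del <- cell & stats::runif(nrow(cohort)) < p_row
      cohort[[it]][del] <- NA_real_
    }
  }
  cohort
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("<simulation_scenario>\n")
  cat("  models:", paste(sprintf("%s (%d orgs x %d clients)", x$models,
      x$n_orgs_per_model[x$models], x$n_clients_per_org[x$models]),
      collapse = ", "), "\n")
  cat("  base cost:", x$base_cost, "| effects:",
      paste(sprintf("%s=%+.0f", names(x$true_model_effects),
                    x$true_model_effects), collapse = ", "), "\n")
  cat("  confounding:",
      paste(sprintf("%s=%.0f/point", names(x$confounding_strength),
                    x$confounding_strength), collapse = ", "), "\n")
  cat("  transitions:",
      paste(sprintf("%s=%.3f", names(x$transition_probs),
                    x$transition_probs), collapse = ", "),
      "| missingness:", x$missingness$mechanism, x$missingness$rate, "\n")
  invisible(x)
}
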