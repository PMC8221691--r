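# Run configuration and the resource-item registry shared by all stages.

# Registry of interRAI-HC style resource-utilization items consumed by the
# costing engine.  Recall periods: 90 days for hospitalization, emergency
# room and physician visits (and the event-type supportive/other items),
# 7 days for regular home care and therapist visits, 3 days for informal
# care.  `unit` controls minute-to-hour conversion before pricing.
carecost_items <- function() {
  data.frame(
    item_key = c("hosp_events", "hosp_days", "er_visits", "phys_visits",
                 "home_care_min", "therapist_min", "supportive_units",
                 "other_hc_units", "informal_min"),
    recall_days = c(90L, 90L, 90L, 90L, 7L, 7L, 90L, 90L, 3L),
    category = c("hospital", "hospital", "visits", "visits", "home_care",
                 "home_care", "supportive", "other_healthcare", "informal"),
    unit = c("event", "day", "event", "event", "minute", "minute",
             "unit", "unit", "minute"),
    price_key = c("hospital_night", "hospital_night", "er_visit",
                  "physician_visit", "home_care_hour", "therapist_hour",
                  "supportive_unit", "other_healthcare_unit",
                  "informal_care_wage"),
    stringsAsFactors = FALSE
  )
}

#' Cost categories used throughout the package
#'
#' The seven cost categories into which valued resource use is accumulated:
#' hospital admissions, emergency-room/physician visits, other healthcare
#' services, supportive care services, institutional care, home care and
#' informal care.  The societal total is their sum; the healthcare total
#' excludes informal care.
#'
#' @return Character vector of the seven category names.
#' @export
cost_categories <- function() {
  c("hospital", "visits", "other_healthcare", "supportive",
    "institutional", "home_care", "informal")
}

#' Run configuration
#'
#' Collects the analysis constants in one validated object: the costing
#' perspective, the number of imputed datasets (default 10), the number of
#' bootstrap replications (default 5000), the significance level (default
#' 0.05), the Spearman collinearity cutoff (default 0.4), the quarter
#' length in days (default 91), and the interpolation weights applied to
#' the baseline and 6-month quarterly costs (default 0.5 and 1.5).
#'
#' @param perspective `"societal"` (all seven categories) or
#'   `"healthcare"` (excludes informal care).
#' @param n_imputations Number of multiply imputed datasets, `m >= 2`.
#' @param n_bootstrap Bootstrap replications for BCa intervals.
#' @param alpha Two-sided significance level in (0, 1).
#' @param collinearity_cutoff Absolute Spearman rho above which a covariate
#'   pair is flagged.
#' @param quarter_days Days per quarter used when scaling recall-period
#'   quantities.
#' @param interpolation_weights Length-2 numeric; weights for the baseline
#'   and month-6 quarterly costs in the 6-month total.  Must sum to 2
#'   (two quarters).
#' @param rng_seed Master seed for every stochastic stage.
#' @param price_table Name of the price table to use.
#' @param countries Codes of the participating countries.
#' @param recorded_days_country Country whose assessments record total
#'   hospital days directly instead of admission counts (Belgium in the
#'   source instrument).
#' @param covariate_priority Case-mix covariates in decreasing priority;
#'   when the collinearity screen flags a pair, the later-listed member is
#'   dropped.
#' @return A list of class `"carecost_config"`.
#' @export
carecost_config <- function(perspective = c("societal", "healthcare"),
                            n_imputations = 10L,
                            n_bootstrap = 5000L,
                            alpha = 0.05,
                            collinearity_cutoff = 0.4,
                            quarter_days = 91L,
                            interpolation_weights = c(0.5, 1.5),
                            rng_seed = 1L,
                            price_table = "dutch_reference",
                            countries = c("BE", "FI", "GE", "IS", "IT", "NL"),
                            recorded_days_country = "BE",
                            covariate_priority = c("age", "sex",
                                                   "living_alone", "cps",
                                                   "drs", "adlh", "iadl",
                                                   "chess")) {
  perspective <- match.arg(perspective)
  stopifnot(is.numeric(n_imputations), n_imputations >= 2,
            is.numeric(n_bootstrap), n_bootstrap >= 1,
            is.numeric(quarter_days), quarter_days > 0)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (length(interpolation_weights) != 2 ||
      abs(sum(interpolation_weights) - 2) > 1e-12)
    stop("interpolation_weights must be two weights summing to 2",
         call. = FALSE)
  if (!recorded_days_country %in% countries)
    stop("recorded_days_country must be one of the configured countries",
         call. = FALSE)
  structure(list(
    perspective = perspective,
    n_imputations = as.integer(n_imputations),
    n_bootstrap = as.integer(n_bootstrap),
    alpha = alpha,
    collinearity_cutoff = collinearity_cutoff,
    quarter_days = as.integer(quarter_days),
    interpolation_weights = as.numeric(interpolation_weights),
    rng_seed = as.integer(rng_seed),
    price_table = price_table,
    countries = countries,
    recorded_days_country = recorded_days_country,
    covariate_priority = covariate_priority
  ), class = "carecost_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [carecost_config()]; absent keys fall back
#' to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"carecost_config"` object.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(carecost_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(carecost_config, raw)
}

#' @export
print.carecost_config <- function(x, ...) {
  cat("<carecost_config>\n")
  cat("  perspective:", x$perspective,
      "| price table:", x$price_table, "\n")
  cat("  m =", x$n_imputations, "imputations, B =", x$n_bootstrap,
      "bootstrap replications, alpha =", x$alpha, "\n")
  cat("  quarter =", x$quarter_days, "days, interpolation weights =",
      paste(x$interpolation_weights, collapse = "/"), "\n")
  invisible(x)
}

# Case-mix covariate columns of a cohort table.
casemix_vars <- function() {
  c("age", "sex", "living_alone", "cps", "drs", "adlh", "iadl", "chess")
}
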