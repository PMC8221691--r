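# Standard unit-cost price tables.
#
# Costs are valued with one uniform price set for all countries so that
# between-model differences reflect resource utilization, not national
# price levels.  Currency is a label only; no conversion is performed.

#' Construct a validated price table
#'
#' A price table holds the standard unit costs for every configured
#' resource item, the hourly wage used to value informal care (proxy-good
#' method: the wage of a legally employed cleaner), per-diem rates for
#' institutional facilities, and country-specific mean hospital lengths of
#' stay used to convert admission counts into nights.  The recorded-days
#' country (where assessments register total hospital days directly) needs
#' no length-of-stay entry.
#'
#' @param name Label for the table (e.g. the reference or an alternate
#'   price set for a sensitivity analysis).
#' @param unit_costs Named numeric: money per unit for each pricing key of
#'   the item registry (`hospital_night`, `er_visit`, `physician_visit`,
#'   `home_care_hour`, `therapist_hour`, `supportive_unit`,
#'   `other_healthcare_unit`).
#' @param informal_care_wage Money per hour of informal care.
#' @param facility_per_diem Named numeric: money per day by facility type.
#' @param hospital_los Named numeric: mean nights per hospital admission by
#'   country code.
#' @param currency Currency label.
#' @param year Price year label.
#' @param countries Countries that must be covered by `hospital_los`.
#' @param recorded_days_country Country exempt from the length-of-stay
#'   requirement.
#' @return A list of class `"price_table"`.
#' @export
price_table <- function(name, unit_costs, informal_care_wage,
                        facility_per_diem, hospital_los,
                        currency = "EUR", year = NA,
                        countries = carecost_config()$countries,
                        recorded_days_country = "BE") {
  unit_costs <- unlist(unit_costs)
  facility_per_diem <- unlist(facility_per_diem)
  hospital_los <- unlist(hospital_los)
  if (missing(informal_care_wage) || is.null(informal_care_wage))
    stop("price table '", name, "' omits informal_care_wage", call. = FALSE)
  needed <- setdiff(unique(carecost_items()$price_key), "informal_care_wage")
  absent <- setdiff(needed, names(unit_costs))
  if (length(absent))
    stop("price table '", name, "' is missing unit costs for: ",
         paste(absent, collapse = ", "), call. = FALSE)
  money <- c(unit_costs, informal_care_wage = unname(informal_care_wage),
             facility_per_diem, hospital_los)
  bad <- names(money)[!is.finite(money) | money < 0]
  if (length(bad))
    stop("price table '", name, "' has negative or non-finite entries: ",
         paste(bad, collapse = ", "), call. = FALSE)
  need_los <- setdiff(countries, recorded_days_country)
  no_los <- setdiff(need_los, names(hospital_los))
  if (length(no_los))
    stop("price table '", name, "' lacks hospital length-of-stay for: ",
         paste(no_los, collapse = ", "), call. = FALSE)
  structure(list(
    name = name, currency = currency, year = year,
    unit_costs = unit_costs,
    informal_care_wage = unname(informal_care_wage),
    facility_per_diem = facility_per_diem,
    hospital_los = hospital_los,
    recorded_days_country = recorded_days_country
  ), class = "price_table")
}

#' Load named price tables from a YAML file
#'
#' The file holds a top-level `tables:` mapping of table name to the
#' fields of [price_table()].  Several named tables (e.g. a reference and
#' an alternate set) may coexist for the price-swap sensitivity analysis;
#' each is retrievable by name from the returned list.
#'
#' @param path YAML file path.
#' @param countries Countries that every table's `hospital_los` must cover.
#' @return Named list of `"price_table"` objects.
#' @export
load_price_tables <- function(path,
                              countries = carecost_config()$countries) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$tables))
    stop("price file must contain a top-level 'tables' mapping",
         call. = FALSE)
  out <- lapply(names(raw$tables), function(nm) {
    entry <- raw$tables[[nm]]
    price_table(
      name = nm,
      unit_costs = entry$unit_costs,
      informal_care_wage = entry$informal_care_wage,
      facility_per_diem = entry$facility_per_diem,
      hospital_los = entry$hospital_los,
      currency = if (is.null(entry$currency)) "EUR" else entry$currency,
      year = if (is.null(entry$year)) NA else entry$year,
      countries = countries,
      recorded_days_country =
        if (is.null(entry$recorded_days_country)) "BE"
        else entry$recorded_days_country
    )
  })
  names(out) <- names(raw$tables)
  out
}

#' Built-in illustrative price tables
#'
#' Returns the synthetic price sets shipped with the package (a
#' Dutch-style reference table and an Italian-style alternate).  These are
#' illustrative values for demonstration and testing only, not a published
#' tariff.
#'
#' @param name Optional table name; when given, that single table is
#'   returned instead of the full list.
#' @return Named list of `"price_table"` objects, or one table.
#' @export
carecost_prices <- function(name = NULL) {
  path <- system.file("extdata", "price_tables_synthetic.yaml",
                      package = "carecost")
  tabs <- load_price_tables(path)
  if (is.null(name)) return(tabs)
  if (!name %in% names(tabs))
    stop("no price table named '", name, "'", call. = FALSE)
  tabs[[name]]
}

#' Scale every monetary entry of a price table
#'
#' Multiplies all unit costs, the informal-care wage and the facility
#' per-diems by `k` (lengths of stay are quantities, not money, and are
#' untouched).  Used for price-sensitivity checks; costing is homogeneous
#' of degree one in prices, so every downstream cost scales by exactly `k`.
#'
#' @param prices A `"price_table"`.
#' @param k Positive scale factor.
#' @return The scaled `"price_table"`.
#' @export
scale_prices <- function(prices, k) {
  stopifnot(inherits(prices, "price_table"), is.numeric(k), k > 0)
  prices$unit_costs <- prices$unit_costs * k
  prices$informal_care_wage <- prices$informal_care_wage * k
  prices$facility_per_diem <- prices$facility_per_diem * k
  prices$name <- paste0(prices$name, "_x", format(k))
  prices
}

#' @export
print.price_table <- function(x, ...) {
  cat("<price_table>", x$name, paste0("(", x$currency,
      if (!is.na(x$year)) paste0(", ", x$year), ")"), "\n")
  cat("  unit costs:\n")
  for (k in names(x$unit_costs))
    cat(sprintf("    %-22s %10.2f\n", k, x$unit_costs[[k]]))
  cat(sprintf("    %-22s %10.2f per hour\n", "informal_care_wage",
              x$informal_care_wage))
  cat("  facility per-diems:",
      paste(sprintf("%s=%.2f", names(x$facility_per_diem),
                    x$facility_per_diem), collapse = ", "), "\n")
  cat("  mean hospital LOS:",
      paste(sprintf("%s=%.1f", names(x$hospital_los), x$hospital_los),
            collapse = ", "),
      sprintf("(recorded days: %s)", x$recorded_days_country), "\n")
  invisible(x)
}
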