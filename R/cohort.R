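# Cohort table I/O and validation.
#
# A cohort is a data.frame with one row per client per assessment wave.
# File dialect (fixed by this package): comma-separated UTF-8, "." as
# decimal mark, empty cell = missing.  Scale scores are ordinal integers;
# non-integer input is rejected, never rounded.

cohort_columns <- function() {
  c("client_id", "org_id", "country", "wave", "age", "sex", "living_alone",
    "cps", "drs", "adlh", "iadl", "chess", "caregiver_distress", "status",
    "facility", carecost_items()$item_key)
}

scale_bounds <- function() {
  list(cps = c(0, 6), drs = c(0, 14), adlh = c(0, 6), iadl = c(0, 48),
       chess = c(0, 5))
}

#' Validate a cohort table
#'
#' Checks the full data model: required columns; `wave` in
#' baseline/month6; `sex`, `status` and `country` from their configured
#' sets; `age >= 65` (cohort definition); integer scale scores within
#' their ranges (CPS 0-6, DRS 0-14, ADLH 0-6, iADL 0-48, CHESS 0-5);
#' non-negative or missing resource quantities; at most one record per
#' client and wave.  Missing quantities are preserved as `NA`, never
#' coerced to zero.
#'
#' @param cohort Data frame with the columns of a cohort table.
#' @param config A [carecost_config()] (supplies the country set).
#' @return The validated cohort, invisibly, with class
#'   `"carecost_cohort"` prepended.
#' @export
validate_cohort <- function(cohort, config = carecost_config()) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  fail <- function(rows, msg) {
    stop(sprintf("row %s: %s", paste(utils::head(rows, 5), collapse = ","),
                 msg), call. = FALSE)
  }
  chk_set <- function(field, allowed) {
    bad <- which(is.na(cohort[[field]]) | !cohort[[field]] %in% allowed)
    if (length(bad))
      fail(bad, sprintf("%s must be one of {%s}", field,
                        paste(allowed, collapse = ", ")))
  }
  chk_set("wave", c("baseline", "month6"))
  chk_set("sex", c("female", "male"))
  chk_set("status", c("in_care", "institutionalized", "deceased",
                      "discharged", "lost"))
  chk_set("country", config$countries)

  bad_age <- which(is.na(cohort$age) | cohort$age < 65)
  if (length(bad_age)) fail(bad_age, "age must be >= 65")

  for (fld in c("living_alone", "caregiver_distress")) {
    v <- cohort[[fld]]
    if (!is.logical(v)) {
      if (is.numeric(v) && all(v %in% c(0, 1, NA))) {
        cohort[[fld]] <- as.logical(v)
      } else fail(which(!v %in% c(TRUE, FALSE, 0, 1)),
                  paste(fld, "must be logical (TRUE/FALSE or 0/1)"))
    }
    if (anyNA(cohort[[fld]]))
      fail(which(is.na(cohort[[fld]])), paste(fld, "must not be missing"))
  }

  for (fld in names(scale_bounds())) {
    b <- scale_bounds()[[fld]]
    v <- cohort[[fld]]
    if (anyNA(v)) fail(which(is.na(v)), paste(fld, "must not be missing"))
    nonint <- which(v != as.integer(v))
    if (length(nonint))
      fail(nonint, sprintf("%s must be an integer score", fld))
    out <- which(v < b[1] | v > b[2])
    if (length(out))
      fail(out, sprintf("%s out of range [%d,%d]", fld, b[1], b[2]))
  }

  for (it in carecost_items()$item_key) {
    v <- cohort[[it]]
    if (!is.numeric(v))
      stop("quantity column '", it, "' must be numeric", call. = FALSE)
    neg <- which(!is.na(v) & v < 0)
    if (length(neg)) fail(neg, sprintf("%s must be missing or >= 0", it))
  }

  dup <- duplicated(cohort[c("client_id", "wave")])
  if (any(dup)) {
    d <- cohort[dup, , drop = FALSE][1, ]
    stop(sprintf("duplicate record for client '%s' at wave '%s'",
                 d$client_id, d$wave), call. = FALSE)
  }

  inst <- cohort$wave == "month6" & cohort$status == "institutionalized"
  no_fac <- which(inst & (is.na(cohort$facility) | cohort$facility == ""))
  if (length(no_fac))
    fail(no_fac, "institutionalized clients need a facility per-diem key")

  if (!inherits(cohort, "carecost_cohort"))
    class(cohort) <- c("carecost_cohort", class(cohort))
  invisible(cohort)
}

#' Read a cohort table from a delimited text file
#'
#' Comma-separated, UTF-8, `.` decimal, empty cell = missing.  Every row
#' must satisfy the data-model invariants (see [validate_cohort()]);
#' otherwise loading stops with a diagnostic naming the row and the
#' violated invariant.
#'
#' @param path File path.
#' @param config A [carecost_config()].
#' @return A validated cohort data frame (class `"carecost_cohort"`).
#' @export
load_cohort <- function(path, config = carecost_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = NA, fileEncoding = "UTF-8")
  for (fld in c("living_alone", "caregiver_distress")) {
    if (is.character(df[[fld]]))
      df[[fld]] <- as.logical(df[[fld]])
  }
  if (is.logical(df$facility)) df$facility <- as.character(df$facility)
  for (it in intersect(carecost_items()$item_key, names(df)))
    df[[it]] <- as.double(df[[it]])   # all-NA columns read as logical
  validate_cohort(df, config)
}

#' Write a cohort table
#'
#' Inverse of [load_cohort()]: numeric values are written with full
#' precision so that a load/write round trip reproduces every numeric
#' field bit-exactly.
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[cohort_columns()]
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Resource-use items of a cohort in long form
#'
#' Unpivots the per-item quantity columns into one row per client, wave
#' and item, attaching each item's recall period, pricing key and cost
#' category from the item registry.
#'
#' @param cohort A cohort data frame.
#' @return Data frame with columns `client_id`, `wave`, `item_key`,
#'   `quantity`, `recall_days`, `category`, `price_key`, `unit`.
#' @export
resource_items <- function(cohort) {
  reg <- carecost_items()
  out <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    data.frame(client_id = cohort$client_id, wave = cohort$wave,
               item_key = reg$item_key[i], quantity = cohort[[reg$item_key[i]]],
               recall_days = reg$recall_days[i], category = reg$category[i],
               price_key = reg$price_key[i], unit = reg$unit[i],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.carecost_cohort <- function(x, ...) {
  n_cli <- length(unique(x$client_id))
  cat(sprintf("<carecost_cohort> %d clients, %d rows, %d organizations, countries: %s\n",
              n_cli, nrow(x), length(unique(x$org_id)),
              paste(sort(unique(x$country)), collapse = " ")))
  st <- table(x$status[x$wave == "month6"])
  cat("  month-6 status:",
      paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  invisible(x)
}
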