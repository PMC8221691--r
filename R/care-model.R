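# Care-model classification of home-care organizations.
#
# Organizations are scored on three core elements of care delivery:
# patient-centred care (PCC, 6 questionnaire items), availability of
# specialized care professionals (ASP, 5 items) and monitoring of care
# performance (MCP, 4 items).  Element scores are item means; higher
# scores indicate a higher focus on that element.  Dichotomized element
# levels map to care models:
#   (PCC, ASP, MCP) = (H,H,H) -> CM1   (H,L,H) -> CM2
#                     (L,L,H) -> CM3   (H,H,L) -> CM4
# The residual patterns, excluded from the benchmark analysis, are mapped
# by a fixed documented rule: (L,H,H) -> CM5; any remaining low-monitoring
# pattern ((H,L,L), (L,H,L), (L,L,L)) -> CM6.

element_items <- function() list(pcc = 6L, asp = 5L, mcp = 4L)

org_item_columns <- function() {
  unlist(lapply(names(element_items()), function(e)
    paste0(e, seq_len(element_items()[[e]]))), use.names = FALSE)
}

#' Validate an organization questionnaire table
#'
#' One row per organization with `org_id` and the 15 item-score columns
#' `pcc1..pcc6`, `asp1..asp5`, `mcp1..mcp4`, each an ordinal score on
#' `0..item_max`.
#'
#' @param orgs Data frame of organization profiles.
#' @param item_max Maximum of the ordinal item scale (default 4).
#' @return `orgs`, invisibly.
#' @export
validate_organizations <- function(orgs, item_max = 4) {
  need <- c("org_id", org_item_columns())
  absent <- setdiff(need, names(orgs))
  if (length(absent))
    stop("organization table is missing columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  for (cl in org_item_columns()) {
    v <- orgs[[cl]]
    if (anyNA(v))
      stop("missing item score in '", cl,
           "' and no imputation policy is defined", call. = FALSE)
    if (any(v < 0 | v > item_max))
      stop("item '", cl, "' outside the 0..", item_max, " scale",
           call. = FALSE)
  }
  if (anyDuplicated(orgs$org_id))
    stop("duplicate org_id in organization table", call. = FALSE)
  invisible(orgs)
}

#' Score the three core elements of care delivery
#'
#' Each element score is the arithmetic mean of its questionnaire items.
#'
#' @inheritParams validate_organizations
#' @return Data frame with `org_id`, `pcc`, `asp`, `mcp`.
#' @export
score_elements <- function(orgs, item_max = 4) {
  validate_organizations(orgs, item_max)
  el <- element_items()
  out <- data.frame(org_id = orgs$org_id, stringsAsFactors = FALSE)
  for (e in names(el)) {
    cols <- paste0(e, seq_len(el[[e]]))
    out[[e]] <- rowMeans(as.matrix(orgs[cols]))
  }
  out
}

#' Classify organizations into care models
#'
#' Element scores are dichotomized at per-element thresholds (default:
#' the scale midpoint `item_max / 2`); a score exactly at the threshold
#' counts as high.  The four level patterns described for the benchmark
#' map to CM1-CM4; residual patterns are assigned CM5/CM6 by the fixed
#' rule documented above and flagged as excluded.
#'
#' @param scores Output of [score_elements()] (or a data frame with
#'   `org_id`, `pcc`, `asp`, `mcp`).
#' @param thresholds Named numeric cutoffs per element; element score
#'   `>= threshold` is "high".
#' @param item_max Maximum of the item scale (sets the default midpoint
#'   thresholds).
#' @return Data frame of class `"care_model_assignment"` with `org_id`,
#'   level columns `pcc_level`, `asp_level`, `mcp_level` ("high"/"low"),
#'   `model` (CM1..CM6) and `excluded` (TRUE for CM5/CM6).
#' @export
classify_care_models <- function(scores,
                                 thresholds = NULL,
                                 item_max = 4) {
  if (is.null(thresholds))
    thresholds <- c(pcc = item_max / 2, asp = item_max / 2,
                    mcp = item_max / 2)
  stopifnot(all(c("pcc", "asp", "mcp") %in% names(scores)),
            all(c("pcc", "asp", "mcp") %in% names(thresholds)))
  if (any(thresholds < 0 | thresholds > item_max))
    stop("thresholds must lie within the item scale", call. = FALSE)
  lev <- function(e)
    ifelse(scores[[e]] >= thresholds[[e]], "high", "low")
  pcc <- lev("pcc"); asp <- lev("asp"); mcp <- lev("mcp")
  pat <- paste0(substr(pcc, 1, 1), substr(asp, 1, 1), substr(mcp, 1, 1))
  model <- c(hhh = "CM1", hlh = "CM2", llh = "CM3", hhl = "CM4",
             lhh = "CM5", hll = "CM6", lhl = "CM6", lll = "CM6")[pat]
  out <- data.frame(org_id = scores$org_id,
                    pcc_level = pcc, asp_level = asp, mcp_level = mcp,
                    model = unname(model),
                    excluded = unname(model) %in% c("CM5", "CM6"),
                    stringsAsFactors = FALSE)
  class(out) <- c("care_model_assignment", class(out))
  out
}

#' One-step classification from an organization table
#'
#' Convenience wrapper: [score_elements()] then [classify_care_models()].
#'
#' @inheritParams validate_organizations
#' @inheritParams classify_care_models
#' @return A `"care_model_assignment"` data frame.
#' @export
assign_care_models <- function(orgs, thresholds = NULL, item_max = 4) {
  classify_care_models(score_elements(orgs, item_max),
                       thresholds = thresholds, item_max = item_max)
}

#' @export
print.care_model_assignment <- function(x, ...) {
  cat("<care_model_assignment>", nrow(x), "organizations\n")
  print(table(model = x$model))
  if (any(x$excluded))
    cat("  (CM5/CM6 organizations are flagged as excluded from",
        "benchmark comparisons)\n")
  invisible(x)
}
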