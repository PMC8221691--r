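# Benchmark report: per-model disaggregated mean costs, category shares,
# informal-to-home-care ratios and adjusted contrasts in one object.
# Tables round money to whole currency units for display; the
# machine-readable output keeps full precision.

#' Assemble a benchmark report
#'
#' Combines the per-model unadjusted cost aggregate and the adjusted
#' comparison into one deterministic report.  The inputs must come from
#' the same run: the breakdown's price table must match the
#' configuration and the comparison's perspective/alpha must match too,
#' otherwise assembly stops with a manifest-mismatch error.  All numbers
#' are carried over from the upstream tables; nothing is recomputed.
#'
#' @param breakdown A complete `"cost_breakdown"` with a `model` column
#'   (or provide `assignments`).
#' @param comparison Optional `"care_model_comparison"` for the adjusted
#'   contrasts (omitted for single-model cohorts).
#' @param config The run's [carecost_config()].
#' @param assignments Optional `"care_model_assignment"` table.
#' @return Object of class `"benchmark_report"` with `per_model`,
#'   `contrasts` and `meta`.
#' @export
build_report <- function(breakdown, comparison = NULL,
                         config = carecost_config(),
                         assignments = NULL) {
  man <- attr(breakdown, "manifest")
  if (!is.null(man)) {
    if (!identical(man$price_table, config$price_table))
      stop("manifest mismatch: breakdown priced with '", man$price_table,
           "' but config expects '", config$price_table, "'",
           call. = FALSE)
    if (!isTRUE(all.equal(man$weights, config$interpolation_weights)))
      stop("manifest mismatch: interpolation weights differ",
           call. = FALSE)
  }
  if (!is.null(comparison)) {
    if (!identical(comparison$perspective, config$perspective))
      stop("manifest mismatch: comparison perspective '",
           comparison$perspective, "' vs config '", config$perspective,
           "'", call. = FALSE)
    if (comparison$alpha != config$alpha)
      stop("manifest mismatch: comparison alpha differs from config",
           call. = FALSE)
  }
  per_model <- aggregate_costs(breakdown, assignments,
                               perspective = config$perspective)
  structure(list(
    per_model = per_model,
    contrasts = if (is.null(comparison)) NULL else comparison$contrasts,
    meta = list(perspective = config$perspective,
                price_table = config$price_table,
                quarter_days = config$quarter_days,
                interpolation_weights = config$interpolation_weights,
                alpha = config$alpha,
                seed = if (is.null(comparison)) config$rng_seed
                       else comparison$seed,
                m = if (is.null(comparison)) NA else comparison$m,
                B = if (is.null(comparison)) NA else comparison$B,
                n_per_model = as.list(stats::setNames(per_model$n,
                                                      per_model$model)))
  ), class = "benchmark_report")
}

#' Write a benchmark report as delimited text
#'
#' `per_model.csv` and (if present) `contrasts.csv` at full precision,
#' plus `meta.yaml` with the run manifest.
#'
#' @param report A `"benchmark_report"`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(report$per_model),
                   file.path(dir, "per_model.csv"), row.names = FALSE)
  if (!is.null(report$contrasts))
    utils::write.csv(report$contrasts,
                     file.path(dir, "contrasts.csv"), row.names = FALSE)
  meta <- report$meta
  meta$n_per_model <- lapply(meta$n_per_model, as.integer)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>", x$meta$perspective, "perspective, price table:",
      x$meta$price_table, "\n\n")
  pm <- as.data.frame(x$per_model)
  money <- grep("^(total_mean|total_se|mean_)", names(pm))
  pm[money] <- lapply(pm[money], round)     # whole currency units
  shares <- grep("^share_", names(pm))
  pm[shares] <- lapply(pm[shares], round, 1)
  if (!is.null(pm$informal_home_ratio))
    pm$informal_home_ratio <- round(pm$informal_home_ratio, 2)
  print(pm, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("\nAdjusted mean cost differences (pooled BCa intervals):\n")
    ct <- x$contrasts
    ct[-1] <- lapply(ct[-1], round)
    print(ct, row.names = FALSE)
  } else cat("\n(no contrasts: single care model)\n")
  invisible(x)
}

#' Stacked bar chart of unadjusted mean costs per care model
#'
#' @param x A `"benchmark_report"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.benchmark_report <- function(x, ...) {
  pm <- as.data.frame(x$per_model)
  cats <- sub("^mean_", "", grep("^mean_", names(pm), value = TRUE))
  mat <- t(as.matrix(pm[paste0("mean_", cats)]))
  rownames(mat) <- cats
  colnames(mat) <- pm$model
  graphics::barplot(mat, legend.text = cats,
                    args.legend = list(x = "topright", cex = 0.7),
                    ylab = sprintf("Mean 6-month %s cost",
                                   x$meta$perspective),
                    col = grDevices::hcl.colors(length(cats), "Spectral"),
                    ...)
  invisible(x)
}
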