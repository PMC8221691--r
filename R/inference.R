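# Case-mix-adjusted comparison of mean 6-month costs between care models.
#
# The estimand is the adjusted mean cost difference between care models:
# ordinary least squares of the 6-month cost on care-model dummies (the
# reference model omitted) plus the case-mix covariates, so each dummy
# coefficient is the adjusted mean difference versus the reference.
# Confidence intervals are BCa bootstrap at the client level; with
# multiply imputed datasets, the bootstrap runs within each completed
# dataset, point estimates are pooled by Rubin's rules, and the
# interval offsets are averaged across imputations and rescaled by
# sqrt(T/W) to carry the between-imputation variance.
# Clustering of clients within organizations is ignored in the variance
# machinery (see the vignette's limitations).

# Coerce case-mix covariates to a numeric data frame (female = 1,
# logicals to 0/1).
numeric_covariates <- function(df, covariates) {
  out <- lapply(covariates, function(p) {
    v <- df[[p]]
    if (identical(p, "sex") && !is.numeric(v)) as.numeric(v == "female")
    else if (is.logical(v)) as.numeric(v)
    else if (!is.numeric(v))
      stop("covariate '", p, "' is not numeric", call. = FALSE)
    else as.numeric(v)
  })
  names(out) <- covariates
  as.data.frame(out)
}

#' Screen case-mix covariates for collinearity
#'
#' Computes Spearman rank correlations between all covariate pairs and
#' flags pairs with `|rho|` above the cutoff (default 0.4).  Of each
#' flagged pair the lower-priority member (the one listed later in
#' `priority`) is dropped; both members are reported.  Constant
#' covariates have undefined rank correlations and are flagged as
#' degenerate (and dropped).
#'
#' @param covariates Data frame of case-mix covariates over clients
#'   (at least 3 rows).
#' @param cutoff Absolute Spearman rho above which a pair is flagged.
#' @param priority Covariate names in decreasing priority.
#' @return A list of class `"collinearity_screen"`: `retained`,
#'   `dropped`, `flagged` (data frame `var1`, `var2`, `rho`),
#'   `degenerate`, `cutoff`.
#' @export
collinearity_screen <- function(covariates, cutoff = 0.4,
                                priority = names(covariates)) {
  if (nrow(covariates) < 3)
    stop("collinearity screening needs at least 3 clients", call. = FALSE)
  X <- numeric_covariates(covariates, names(covariates))
  degenerate <- names(X)[vapply(X, function(v)
    length(unique(v)) < 2, logical(1))]
  rho <- suppressWarnings(stats::cor(as.matrix(X), method = "spearman"))

  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(rho)[pairs[, 1]],
                        var2 = colnames(rho)[pairs[, 2]],
                        rho = rho[pairs], stringsAsFactors = FALSE)
  flagged <- flagged[!is.na(flagged$rho) & abs(flagged$rho) > cutoff, ,
                     drop = FALSE]
  rownames(flagged) <- NULL

  ord <- match(names(X), priority)
  retained <- setdiff(names(X), degenerate)
  repeat {
    live <- flagged[flagged$var1 %in% retained &
                    flagged$var2 %in% retained, , drop = FALSE]
    if (!nrow(live)) break
    pair <- live[1, ]
    drop_var <- if (ord[match(pair$var1, names(X))] >
                    ord[match(pair$var2, names(X))]) pair$var1
                else pair$var2
    retained <- setdiff(retained, drop_var)
  }
  structure(list(retained = retained,
                 dropped = setdiff(names(X), retained),
                 flagged = flagged, degenerate = degenerate,
                 cutoff = cutoff),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("<collinearity_screen> cutoff |rho| >", x$cutoff, "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped: ", paste(x$dropped, collapse = ", "), "\n")
  if (nrow(x$flagged)) {
    cat("  flagged pairs:\n")
    print(x$flagged)
  }
  if (length(x$degenerate))
    cat("  degenerate (constant):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

# Build the OLS design matrix: intercept, care-model dummies (reference
# omitted), covariates.  Returns list(X, y, dummy_cols, models, reference).
build_design <- function(data, outcome, covariates, reference) {
  models <- sort(unique(data$model))
  if (length(models) < 2)
    stop("need at least 2 care models to compare", call. = FALSE)
  if (!reference %in% models)
    stop("reference model '", reference, "' not present", call. = FALSE)
  others <- setdiff(models, reference)
  D <- vapply(others, function(mdl) as.numeric(data$model == mdl),
              numeric(nrow(data)))
  colnames(D) <- paste0("model", others)
  X <- cbind(`(Intercept)` = 1, D)
  if (length(covariates))
    X <- cbind(X, as.matrix(numeric_covariates(data, covariates)))
  y <- data[[outcome]]
  if (anyNA(y))
    stop("outcome '", outcome, "' has missing values; impute first",
         call. = FALSE)
  list(X = X, y = y, dummy_cols = colnames(D), models = models,
       reference = reference)
}

#' Fit the case-mix-adjusted cost model on one completed dataset
#'
#' Ordinary least squares of the 6-month cost on care-model dummy
#' variables (reference model omitted) plus the case-mix covariates.
#' The dummy coefficients are the adjusted mean cost differences of each
#' model versus the reference.
#'
#' @param data Completed cost breakdown with a `model` column.
#' @param covariates Case-mix covariate names (default: the eight
#'   adjustment variables age, sex, living_alone, CPS, DRS, ADLH, iADL,
#'   CHESS).
#' @param reference Reference care model (default: the model with the
#'   lowest unadjusted mean cost).
#' @param outcome Outcome column (`total_societal_6m` or
#'   `total_healthcare_6m`).
#' @return Object of class `"adjusted_fit"`: coefficients, fitted
#'   values, residuals, the design matrix, dummy-column names and the
#'   reference model.
#' @export
fit_adjusted_model <- function(data, covariates = casemix_vars(),
                               reference = NULL,
                               outcome = "total_societal_6m") {
  if (is.null(reference)) {
    mm <- tapply(data[[outcome]], data$model, mean)
    reference <- names(mm)[which.min(mm)]
  }
  des <- build_design(data, outcome, covariates, reference)
  qr_x <- qr(des$X)
  if (qr_x$rank < ncol(des$X)) {
    bad <- colnames(des$X)[qr_x$pivot[(qr_x$rank + 1):ncol(des$X)]]
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, des$y)
  fitted <- drop(des$X %*% beta)
  structure(list(coefficients = beta, fitted.values = fitted,
                 residuals = des$y - fitted, X = des$X, y = des$y,
                 dummy_cols = des$dummy_cols, models = des$models,
                 reference = reference, covariates = covariates,
                 outcome = outcome),
            class = "adjusted_fit")
}

#' @export
coef.adjusted_fit <- function(object, ...) object$coefficients

#' @export
residuals.adjusted_fit <- function(object, ...) object$residuals

#' @export
print.adjusted_fit <- function(x, ...) {
  cat("<adjusted_fit> OLS of", x$outcome, "on care-model dummies +",
      length(x$covariates), "covariates; reference:", x$reference, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

# All pairwise contrasts among the models, reference first.  Returns a
# data.frame with columns a, b (contrast a - b) and a label.
contrast_table <- function(models, reference) {
  others <- setdiff(models, reference)
  rows <- data.frame(a = others, b = reference,
                     stringsAsFactors = FALSE)
  if (length(others) > 1) {
    cmb <- utils::combn(sort(others), 2)
    rows <- rbind(rows, data.frame(a = cmb[2, ], b = cmb[1, ],
                                   stringsAsFactors = FALSE))
  }
  rows$label <- paste(rows$a, "-", rows$b)
  rows
}

# Contrast estimates from a coefficient vector (reference coef = 0).
contrast_estimates <- function(beta, dummy_cols, contrasts, reference) {
  get <- function(mdl) if (mdl == reference) 0
                       else beta[[paste0("model", mdl)]]
  vapply(seq_len(nrow(contrasts)), function(k)
    get(contrasts$a[k]) - get(contrasts$b[k]), numeric(1))
}

# Exact leave-one-out OLS contrast values via the downdating identity
# beta(-i) = beta - (X'X)^{-1} x_i e_i / (1 - h_i).
jackknife_contrasts <- function(X, y, beta, contrasts, dummy_cols,
                                reference) {
  XtX_inv <- chol2inv(chol(crossprod(X)))
  G <- X %*% XtX_inv                       # n x p
  h <- rowSums(G * X)
  e <- y - drop(X %*% beta)
  delta <- G * (e / (1 - h))               # row i = beta - beta(-i)
  colnames(delta) <- colnames(X)
  K <- nrow(contrasts)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    ca <- contrasts$a[k]; cb <- contrasts$b[k]
    d <- numeric(nrow(X))
    if (ca != reference) d <- d + delta[, paste0("model", ca)]
    if (cb != reference) d <- d - delta[, paste0("model", cb)]
    t0 <- (if (ca == reference) 0 else beta[[paste0("model", ca)]]) -
          (if (cb == reference) 0 else beta[[paste0("model", cb)]])
    out[, k] <- t0 - d
  }
  out
}

#' Compare care models on case-mix-adjusted mean costs
#'
#' The package's main fitting function.  Within each completed
#' (imputed) dataset it fits the adjusted cost model, bootstraps the
#' clients (stratified guard: resamples missing a care model are
#' redrawn) to obtain BCa confidence intervals for every pairwise
#' adjusted mean cost difference, and then pools across imputations:
#' point estimates by Rubin's rules (bootstrap variances as the
#' within-imputation variances); the interval is the average of the
#' per-imputation BCa offsets around the pooled estimate, rescaled by
#' `sqrt(T/W)` so it carries the between-imputation variance Rubin's
#' total variance requires.  The reference is the care model with the
#' lowest unadjusted mean cost unless overridden.  Covariates first pass
#' the Spearman collinearity screen.
#'
#' @param costs An `"imputed_costs"` object, a list of completed cost
#'   breakdowns, or a single complete breakdown (then no Rubin pooling
#'   is involved).
#' @param assignments Optional `"care_model_assignment"` table used to
#'   attach `model` by `org_id`; organizations flagged as excluded
#'   (CM5/CM6) are dropped with a message.
#' @param covariates Case-mix covariate names.
#' @param perspective `"societal"` or `"healthcare"` (selects the
#'   outcome total).
#' @param reference Reference care model; default lowest-cost.
#' @param B Bootstrap replications per imputed dataset.
#' @param alpha Significance level of the `1 - alpha` intervals.
#' @param seed Master seed; the per-imputation bootstrap streams are
#'   derived from it deterministically.
#' @param collinearity_cutoff Spearman cutoff for the covariate screen.
#' @param covariate_priority Priority order for dropping flagged
#'   covariates.
#' @return Object of class `"care_model_comparison"`; see
#'   [print.care_model_comparison()], [summary.care_model_comparison()],
#'   [coef.care_model_comparison()], [confint.care_model_comparison()],
#'   [plot.care_model_comparison()].
#' @export
compare_care_models <- function(costs, assignments = NULL,
                                covariates = casemix_vars(),
                                perspective = c("societal", "healthcare"),
                                reference = NULL,
                                B = 5000L, alpha = 0.05, seed = 1L,
                                collinearity_cutoff = 0.4,
                                covariate_priority = covariates) {
  perspective <- match.arg(perspective)
  outcome <- if (perspective == "healthcare") "total_healthcare_6m"
             else "total_societal_6m"

  datasets <- if (inherits(costs, "imputed_costs")) costs$datasets
              else if (is.data.frame(costs)) list(costs)
              else costs
  m <- length(datasets)
  datasets <- lapply(datasets, function(d) {
    d <- as.data.frame(d)
    if (!is.null(assignments)) {
      d$model <- assignments$model[match(d$org_id, assignments$org_id)]
      if (any(assignments$excluded)) {
        excl <- assignments$model[assignments$excluded]
        keep <- !d$model %in% excl
        if (any(!keep))
          message(sum(!keep), " clients in excluded care models (",
                  paste(unique(excl), collapse = ", "), ") dropped")
        d <- d[keep, , drop = FALSE]
      }
    }
    if (is.null(d$model))
      stop("datasets need a 'model' column or an assignments table",
           call. = FALSE)
    d
  })

  d1 <- datasets[[1]]
  screen <- collinearity_screen(d1[covariates],
                                cutoff = collinearity_cutoff,
                                priority = covariate_priority)
  use_cov <- screen$retained

  if (is.null(reference)) {
    pooled_means <- Reduce(`+`, lapply(datasets, function(d)
      tapply(d[[outcome]], d$model, mean))) / m
    reference <- names(pooled_means)[which.min(pooled_means)]
  }

  des1 <- build_design(d1, outcome, use_cov, reference)
  models <- des1$models
  contrasts <- contrast_table(models, reference)
  K <- nrow(contrasts)
  n <- nrow(d1)
  model_int <- match(d1$model, models)
  n_models <- length(models)

  est <- matrix(NA_real_, m, K)
  w_var <- matrix(NA_real_, m, K)
  lo <- matrix(NA_real_, m, K)
  hi <- matrix(NA_real_, m, K)

  for (d in seq_len(m)) {
    des <- build_design(datasets[[d]], outcome, use_cov, reference)
    X <- des$X; y <- des$y
    fit0 <- qr(X)
    if (fit0$rank < ncol(X)) {
      bad <- colnames(X)[fit0$pivot[(fit0$rank + 1):ncol(X)]]
      stop("design matrix is rank deficient; offending columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(fit0, y)
    t0 <- contrast_estimates(beta, des$dummy_cols, contrasts, reference)

    set.seed(seed + d)            # deterministic per-imputation substream
    t_boot <- matrix(NA_real_, B, K)
    for (b in seq_len(B)) {
      for (try in 1:100) {
        ix <- sample.int(n, n, replace = TRUE)
        if (min(tabulate(model_int[ix], n_models)) == 0L) next
        bb <- tryCatch(
          solve(crossprod(X[ix, , drop = FALSE]),
                crossprod(X[ix, , drop = FALSE], y[ix])),
          error = function(e) NULL)
        if (is.null(bb)) next
        bvec <- drop(bb); names(bvec) <- colnames(X)
        t_boot[b, ] <- contrast_estimates(bvec, des$dummy_cols,
                                          contrasts, reference)
        break
      }
      if (anyNA(t_boot[b, ]))
        stop("could not draw an admissible resample in 100 tries",
             call. = FALSE)
    }
    t_jack <- jackknife_contrasts(X, y, beta, contrasts,
                                  des$dummy_cols, reference)
    for (k in seq_len(K)) {
      ci <- bca_interval(t0[k], t_boot[, k], t_jack[, k], alpha)
      est[d, k] <- t0[k]
      w_var[d, k] <- stats::var(t_boot[, k])
      lo[d, k] <- ci[1]; hi[d, k] <- ci[2]
    }
  }

  pooled <- lapply(seq_len(K), function(k) {
    if (m >= 2) pool_rubin(est[, k], w_var[, k])
    else structure(list(estimate = est[1, k], W = w_var[1, k], B = 0,
                        T = w_var[1, k], se = sqrt(w_var[1, k]), m = 1),
                   class = "pooled_result")
  })
  # combine intervals across imputations: average the per-imputation
  # BCa offsets around their estimates, then rescale by sqrt(T/W) so
  # the pooled interval carries the between-imputation component that
  # Rubin's total variance requires (reduces to plain bound-averaging
  # when the datasets agree, i.e. T = W)
  ci_low <- ci_high <- numeric(K)
  for (k in seq_len(K)) {
    p <- pooled[[k]]
    infl <- if (p$W > 0) sqrt(p$T / p$W) else 1
    ci_low[k] <- p$estimate + mean(lo[, k] - est[, k]) * infl
    ci_high[k] <- p$estimate + mean(hi[, k] - est[, k]) * infl
  }
  tab <- data.frame(contrast = contrasts$label,
                    estimate = vapply(pooled, `[[`, numeric(1),
                                      "estimate"),
                    ci_low = ci_low, ci_high = ci_high,
                    se = vapply(pooled, `[[`, numeric(1), "se"),
                    stringsAsFactors = FALSE)

  structure(list(contrasts = tab, pooled = pooled,
                 per_imputation = list(estimates = est, lo = lo, hi = hi,
                                       within_var = w_var),
                 contrast_pairs = contrasts,
                 reference = reference, models = models,
                 n_per_model = table(d1$model),
                 covariates = use_cov, screen = screen,
                 perspective = perspective, outcome = outcome,
                 m = m, B = B, alpha = alpha, seed = seed,
                 n = n),
            class = "care_model_comparison")
}

#' @export
print.care_model_comparison <- function(x, ...) {
  cat(sprintf("<care_model_comparison> %s perspective, %d clients, reference: %s\n",
              x$perspective, x$n, x$reference))
  cat(sprintf("  m = %d imputations, B = %d bootstrap replications, %d%% BCa intervals\n",
              x$m, x$B, round(100 * (1 - x$alpha))))
  tab <- x$contrasts
  tab[-1] <- lapply(tab[-1], round, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.care_model_comparison <- function(object, ...) {
  structure(list(comparison = object), class = "summary.care_model_comparison")
}

#' @export
print.summary.care_model_comparison <- function(x, ...) {
  cmp <- x$comparison
  print(cmp)
  cat("\nClients per model:\n")
  print(cmp$n_per_model)
  cat("\nAdjustment covariates after collinearity screen:\n  ",
      paste(cmp$covariates, collapse = ", "), "\n")
  if (nrow(cmp$screen$flagged)) {
    cat("Flagged covariate pairs (|rho| >", cmp$screen$cutoff, "):\n")
    print(cmp$screen$flagged)
  }
  cat("\nRubin pooling per contrast:\n")
  for (k in seq_along(cmp$pooled)) {
    p <- cmp$pooled[[k]]
    cat(sprintf("  %-12s estimate %10.2f  W %12.2f  B %12.2f  T %12.2f\n",
                cmp$contrasts$contrast[k], p$estimate, p$W, p$B, p$T))
  }
  invisible(x)
}

#' @export
coef.care_model_comparison <- function(object, ...) {
  stats::setNames(object$contrasts$estimate, object$contrasts$contrast)
}

#' Confidence bounds of the pooled contrasts
#'
#' Returns the averaged per-imputation BCa bounds computed at fit time;
#' `level` must match the `alpha` the object was fitted with (BCa bounds
#' are not recomputable from the stored summary).
#'
#' @param object A `"care_model_comparison"`.
#' @param parm Optional contrast labels to subset.
#' @param level Confidence level (must equal `1 - alpha` of the fit).
#' @param ... Unused.
#' @return Matrix with columns `ci_low`, `ci_high`.
#' @export
confint.care_model_comparison <- function(object, parm = NULL,
                                          level = 1 - object$alpha, ...) {
  if (abs(level - (1 - object$alpha)) > 1e-12)
    stop("intervals were computed at level ", 1 - object$alpha,
         "; refit to change it", call. = FALSE)
  tab <- object$contrasts
  if (!is.null(parm)) tab <- tab[tab$contrast %in% parm, , drop = FALSE]
  out <- as.matrix(tab[c("ci_low", "ci_high")])
  rownames(out) <- tab$contrast
  out
}

#' Forest-style plot of adjusted cost differences
#'
#' Point estimates with their pooled BCa intervals, one row per
#' contrast, with a zero reference line.
#'
#' @param x A `"care_model_comparison"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.care_model_comparison <- function(x, ...) {
  tab <- x$contrasts
  k <- nrow(tab)
  yl <- rev(seq_len(k))
  rng <- range(0, tab$ci_low, tab$ci_high)
  op <- graphics::par(mar = c(4.5, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tab$estimate, yl, xlim = rng, ylim = c(0.5, k + 0.5),
                 pch = 16, yaxt = "n",
                 xlab = sprintf("Adjusted mean %s cost difference",
                                x$perspective),
                 ylab = "", ...)
  graphics::segments(tab$ci_low, yl, tab$ci_high, yl)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  graphics::axis(2, at = yl, labels = tab$contrast, las = 1)
  invisible(x)
}
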