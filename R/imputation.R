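# Multiple imputation of missing cost data by chained equations with
# predictive mean matching (PMM), and Rubin's rules for pooling.
#
# Imputation operates on the wave-level quarterly category costs (the
# q1_*/q2_* columns of a cost breakdown), before the 6-month
# interpolation, so the interpolation identity holds exactly in every
# completed dataset.  PMM replaces each missing value with an observed
# donor value whose OLS-predicted mean is among the closest, so imputed
# values always lie within the observed support -- the property that
# makes PMM suitable for right-skewed cost data.

# One chained-equations pass over the variables with missing cells.
# For each target variable in declared order: OLS of the observed values
# on the predictors plus the other (currently completed) cost variables.
# Observed cells are predicted from the least-squares fit; the
# missing-cell predictions use a Bayesian draw of the regression
# parameters (scaled inverse-chi-squared sigma^2, normal beta), which is
# what makes the imputation "proper": the m datasets carry genuine
# between-imputation variability.  Each missing cell then draws
# uniformly from the `donors` observed values with the closest
# predicted means.
pmm_update <- function(data, var, miss_idx, predictors, donors) {
  obs_idx <- setdiff(seq_len(nrow(data)), miss_idx)
  X <- cbind(1, as.matrix(data[predictors]))
  y <- data[[var]]
  Xo <- X[obs_idx, , drop = FALSE]
  fit <- stats::lm.fit(Xo, y[obs_idx])
  keep <- !is.na(fit$coefficients)
  beta <- fit$coefficients[keep]
  Xk <- Xo[, keep, drop = FALSE]
  pred_obs <- drop(Xk %*% beta)

  p <- sum(keep)
  df <- max(length(obs_idx) - p, 1)
  rss <- sum(fit$residuals^2)
  if (rss > 0) {
    sigma_star <- sqrt(rss / stats::rchisq(1, df))
    R <- qr.R(qr(Xk))
    beta_star <- beta + sigma_star *
      drop(backsolve(R, stats::rnorm(p)))
  } else beta_star <- beta        # degenerate (e.g. constant donors)
  pred_mis <- drop(X[miss_idx, keep, drop = FALSE] %*% beta_star)

  k <- min(donors, length(obs_idx))
  for (j in seq_along(miss_idx)) {
    d <- abs(pred_obs - pred_mis[j])
    pool <- obs_idx[order(d)[seq_len(k)]]
    data[[var]][miss_idx[j]] <- y[pool[sample.int(k, 1L)]]
  }
  data
}

#' Impute missing cost data (chained equations with PMM)
#'
#' Builds `m` completed datasets from a per-client cost breakdown whose
#' wave-level category costs contain missing cells.  The chained
#' equations visit the incomplete cost variables in a fixed declared
#' order (column order of the breakdown); each update regresses the
#' observed values on the fully observed baseline case-mix predictors
#' plus the other cost variables at their current values, and fills each
#' missing cell with a uniformly drawn donor from the `donors` observed
#' values closest in predicted mean.  Missing cells are initialized with
#' random draws from the observed values.  The result is deterministic
#' under `seed`; the `m` datasets differ only in imputed cells, and the
#' 6-month category costs and totals are recomputed in each so the
#' interpolation identity holds throughout.
#'
#' @param breakdown A `"cost_breakdown"` data frame (see
#'   [client_costs()]).
#' @param m Number of imputed datasets (default 10).
#' @param predictors Baseline covariates used in every imputation model;
#'   must be fully observed.
#' @param maxit Chained-equation iterations per dataset.
#' @param donors Size of the PMM donor pool (default 5).
#' @param seed Integer seed.
#' @param weights Interpolation weights used to recompute 6-month costs.
#' @return An object of class `"imputed_costs"`: a list with `datasets`
#'   (list of `m` completed breakdowns), `m`, `imputed_cells`, `seed`.
#' @export
impute_costs <- function(breakdown, m = 10L,
                         predictors = casemix_vars(),
                         maxit = 5L, donors = 5L, seed = 1L,
                         weights = c(0.5, 1.5)) {
  stopifnot(m >= 2, donors >= 1, maxit >= 1)
  cats <- cost_categories()
  cost_vars <- c(paste0("q1_", cats), paste0("q2_", cats))
  cost_vars <- intersect(cost_vars, names(breakdown))

  work <- as.data.frame(breakdown)
  work$sex_num <- as.numeric(work$sex == "female")
  pred_num <- vapply(predictors, function(p) {
    if (p == "sex") "sex_num"
    else if (is.logical(work[[p]])) {
      work[[paste0(p, "_num")]] <<- as.numeric(work[[p]])
      paste0(p, "_num")
    } else p
  }, character(1))
  if (anyNA(work[pred_num]))
    stop("imputation predictors must be fully observed", call. = FALSE)

  miss <- lapply(cost_vars, function(v) which(is.na(work[[v]])))
  names(miss) <- cost_vars
  all_missing <- cost_vars[vapply(miss, length, integer(1)) == nrow(work)]
  if (length(all_missing))
    stop("no observed donors for: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  to_impute <- cost_vars[vapply(miss, length, integer(1)) > 0]

  set.seed(seed)
  datasets <- vector("list", m)
  for (d in seq_len(m)) {
    cur <- work
    # initialize missing cells by random draws from the observed values
    for (v in to_impute) {
      obs <- cur[[v]][-miss[[v]]]
      cur[[v]][miss[[v]]] <- sample(obs, length(miss[[v]]),
                                    replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in to_impute) {
        others <- setdiff(cost_vars, v)
        cur <- pmm_update(cur, v, miss[[v]],
                          predictors = c(unname(pred_num), others),
                          donors = donors)
      }
    }
    done <- cur[setdiff(names(cur),
                        grep("_num$", names(cur), value = TRUE))]
    done <- recompute_totals(done, weights)
    class(done) <- class(breakdown)
    attr(done, "manifest") <- attr(breakdown, "manifest")
    datasets[[d]] <- done
  }
  structure(list(datasets = datasets, m = m,
                 imputed_cells = miss[to_impute],
                 predictors = predictors, donors = donors,
                 maxit = maxit, seed = seed),
            class = "imputed_costs")
}

#' @export
print.imputed_costs <- function(x, ...) {
  ncell <- sum(vapply(x$imputed_cells, length, integer(1)))
  cat(sprintf("<imputed_costs> m = %d datasets, %d imputed cells in %d variables (PMM, %d donors, %d iterations, seed %d)\n",
              x$m, ncell, length(x$imputed_cells), x$donors, x$maxit,
              x$seed))
  invisible(x)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Pooled point estimate: the mean of the per-dataset estimates.
#' Within-imputation variance `W`: the mean of the per-dataset
#' variances.  Between-imputation variance `B`: the sample variance of
#' the estimates.  Total variance `T = W + (1 + 1/m) B`.
#'
#' @param estimates Numeric vector of `m >= 2` per-dataset estimates.
#' @param variances Numeric vector of their `m` variances.
#' @return A list of class `"pooled_result"` with `estimate`, `W`, `B`,
#'   `T`, `se = sqrt(T)` and `m`.
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m)
    stop("pooling needs m >= 2 estimates with matching variances",
         call. = FALSE)
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  structure(list(estimate = mean(estimates), W = W, B = B, T = Tv,
                 se = sqrt(Tv), m = m),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("<pooled_result> estimate %.4f (se %.4f), m = %d, W = %.4f, B = %.4f, T = %.4f\n",
              x$estimate, x$se, x$m, x$W, x$B, x$T))
  invisible(x)
}
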