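# Bias-corrected accelerated (BCa) bootstrap confidence intervals.
#
# Conventions fixed here and pinned by the exhaustive-enumeration oracle
# in the test suite:
#  * bias-correction constant: z0 = qnorm((#{t* < t0} + 0.5 #{t* = t0}) / B),
#    i.e. ties with the point estimate count half (relevant when the
#    resample distribution has atoms, as under enumeration);
#  * acceleration from the jackknife: with L_i = mean(t_jack) - t_jack_i,
#    a = sum(L^3) / (6 * sum(L^2)^{3/2}) (0 if all L are 0);
#  * adjusted percentile levels alpha_k = pnorm(z0 + (z0 + z_k)/(1 - a (z0 + z_k)))
#    for z_k = qnorm(alpha/2), qnorm(1 - alpha/2);
#  * interval endpoints are empirical quantiles of the resample
#    distribution with linear interpolation (stats::quantile type 7).
# With z0 = 0 and a = 0 the interval reduces to the percentile interval.

# Core computation from replicate values.  t0: point estimate;
# t: bootstrap replicates; t_jack: jackknife leave-one-out values.
bca_interval <- function(t0, t, t_jack, alpha = 0.05) {
  t <- t[is.finite(t)]
  B <- length(t)
  if (B == 0) stop("no finite bootstrap replicates", call. = FALSE)
  if (all(t == t[1])) {
    warning("degenerate resample distribution; returning the point value",
            call. = FALSE)
    return(structure(c(t0, t0), z0 = 0, accel = 0,
                     levels = c(NA_real_, NA_real_)))
  }
  p <- (sum(t < t0) + 0.5 * sum(t == t0)) / B
  if (p <= 0 || p >= 1) {
    warning("all bootstrap replicates on one side of the estimate; ",
            "bias correction clamped", call. = FALSE)
    p <- min(max(p, 1 / (B + 1)), B / (B + 1))
  }
  z0 <- stats::qnorm(p)
  L <- mean(t_jack) - t_jack
  s2 <- sum(L^2)
  a <- if (s2 == 0) 0 else sum(L^3) / (6 * s2^1.5)
  zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  lev <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- stats::quantile(t, probs = lev, type = 7, names = FALSE)
  structure(ci, z0 = z0, accel = a, levels = lev)
}

#' BCa bootstrap confidence interval for a statistic
#'
#' Nonparametric bootstrap at the observation (client) level: resamples
#' of the original size are drawn with replacement, the bias-correction
#' constant comes from the fraction of resample statistics below the
#' point estimate, the acceleration from the jackknife skewness, and the
#' interval endpoints are the BCa-adjusted percentiles of the resample
#' distribution.  Deterministic under `seed`.
#'
#' With `enumerate = TRUE` all `n^n` index resamples are evaluated
#' instead of Monte-Carlo draws (small `n` only); the replicate set is
#' then exhaustive and seed-free.
#'
#' @param data Vector or data frame of observations (rows resampled).
#' @param statistic Function `statistic(data, idx)` returning a scalar.
#' @param B Bootstrap replications (default 5000).
#' @param alpha Significance level; the interval has nominal coverage
#'   `1 - alpha`.
#' @param seed Integer seed (ignored when enumerating).
#' @param enumerate Evaluate every possible resample instead of sampling.
#' @param guard Optional predicate `guard(idx)`; resamples for which it
#'   returns `FALSE` are redrawn (e.g. to keep every care model
#'   represented).
#' @return Length-2 numeric `(low, high)` with attributes `z0`, `accel`,
#'   `levels`, `t0` and `B`.
#' @export
bca_ci <- function(data, statistic, B = 5000L, alpha = 0.05,
                   seed = NULL, enumerate = FALSE, guard = NULL) {
  n <- if (is.data.frame(data) || is.matrix(data)) nrow(data)
       else length(data)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  t0 <- statistic(data, seq_len(n))

  if (enumerate) {
    if (n^n > 1e6)
      stop("enumeration over ", n, "^", n, " resamples is infeasible",
           call. = FALSE)
    idx_grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n),
                                      KEEP.OUT.ATTRS = FALSE))
    t <- apply(idx_grid, 1L, function(ix) statistic(data, ix))
  } else {
    if (!is.null(seed)) set.seed(seed)
    t <- vapply(seq_len(B), function(b) {
      for (try in 1:100) {
        ix <- sample.int(n, n, replace = TRUE)
        if (is.null(guard) || isTRUE(guard(ix)))
          return(statistic(data, ix))
      }
      stop("could not draw an admissible resample in 100 tries",
           call. = FALSE)
    }, numeric(1))
  }

  t_jack <- vapply(seq_len(n), function(i)
    statistic(data, seq_len(n)[-i]), numeric(1))

  ci <- bca_interval(t0, t, t_jack, alpha)
  attr(ci, "t0") <- t0
  attr(ci, "B") <- length(t)
  ci
}
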