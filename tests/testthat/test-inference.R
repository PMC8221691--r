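# Collinearity screening, adjusted regression, BCa bootstrap, and the
# pooled care-model comparison.

test_that("collinearity screen flags monotone pairs and drops by priority", {
  set.seed(5)
  x <- runif(300)
  cov <- data.frame(a = x, b = exp(x), c = runif(300), d = -x)
  sc <- collinearity_screen(cov, cutoff = 0.4,
                            priority = c("a", "b", "c", "d"))
  # a~b monotone (rho = 1) and a~d antitone (rho = -1): both flagged
  expect_true(any(sc$flagged$var1 == "a" & sc$flagged$var2 == "b" &
                  sc$flagged$rho == 1))
  expect_true(any(sc$flagged$var1 == "a" & sc$flagged$var2 == "d" &
                  sc$flagged$rho == -1))
  expect_setequal(sc$retained, c("a", "c"))   # lower-priority b, d drop
})

test_that("independent covariates pass the screen; constants are degenerate", {
  set.seed(11)
  cov <- as.data.frame(matrix(runif(1000 * 5), 1000, 5))
  sc <- collinearity_screen(cov)
  expect_identical(nrow(sc$flagged), 0L)
  expect_setequal(sc$retained, names(cov))

  cov$flat <- 1
  sc2 <- collinearity_screen(cov)
  expect_identical(sc2$degenerate, "flat")
  expect_false("flat" %in% sc2$retained)
  expect_error(collinearity_screen(cov[1:2, ]), "at least 3")
})

test_that("adjusted OLS reduces to group-mean differences and matches normal equations", {
  d <- data.frame(model = rep(c("A", "B"), each = 5),
                  total_societal_6m = c(rnorm(5, 100), rnorm(5, 250)))
  f <- fit_adjusted_model(d, covariates = character(0), reference = "A")
  expect_equal(unname(coef(f)["modelB"]),
               mean(d$total_societal_6m[d$model == "B"]) -
               mean(d$total_societal_6m[d$model == "A"]))

  dz <- d; dz$total_societal_6m <- 77
  fz <- fit_adjusted_model(dz, covariates = character(0),
                           reference = "A")
  expect_equal(unname(coef(fz)), c(77, 0))

  # instances with <= 10 clients vs an explicit normal-equations solve
  set.seed(13)
  for (r in 1:20) {
    n <- sample(6:10, 1)
    dd <- data.frame(model = c("A", "B", sample(c("A", "B"), n - 2,
                                                replace = TRUE)),
                     age = runif(n, 65, 95), adlh = sample(0:6, n, TRUE),
                     total_societal_6m = rlnorm(n, 9, 0.5))
    f <- fit_adjusted_model(dd, covariates = c("age", "adlh"),
                            reference = "A")
    want <- oracle_normal_equations(f$X, f$y)
    expect_equal(unname(coef(f)), unname(want), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail with the offending column named", {
  d <- data.frame(model = rep(c("A", "B"), each = 5),
                  age = 70, adlh = rep(2, 10),
                  total_societal_6m = rnorm(10, 100))
  expect_error(fit_adjusted_model(d, covariates = c("age", "adlh"),
                                  reference = "A"),
               "rank deficient.*adlh")
  expect_error(fit_adjusted_model(d[d$model == "A", ],
                                  covariates = character(0)),
               "at least 2 care models")
})

test_that("BCa handles degenerate data and reduces to the percentile interval", {
  expect_warning(ci <- bca_ci(rep(5, 10), function(x, i) mean(x[i]),
                              B = 50, seed = 1),
                 "degenerate")
  expect_equal(unname(ci[1:2]), c(5, 5))

  # symmetric replicate set with median at t0 and symmetric jackknife:
  # z0 = 0, a = 0, so the interval is the plain percentile interval
  t0 <- 0
  t <- c(-(50:1), 0, 1:50) / 10
  tj <- c(-(5:1), 0, 1:5)
  ci <- carecost:::bca_interval(t0, t, tj, alpha = 0.1)
  expect_equal(attr(ci, "z0"), 0)
  expect_equal(attr(ci, "accel"), 0)
  expect_equal(unname(ci[1:2]),
               unname(quantile(t, c(0.05, 0.95), type = 7)))
})

test_that("BCa agrees with the boot package on a skewed sample", {
  skip_if_not_installed("boot")
  set.seed(101)
  x <- rlnorm(120, 5, 0.8)
  ours <- bca_ci(x, function(d, i) mean(d[i]), B = 4000, seed = 3)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  bci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  # same method, different resample streams and percentile conventions
  halfwidth <- (ours[2] - ours[1]) / 2
  expect_lt(abs(ours[1] - bci[1]), 0.15 * halfwidth)
  expect_lt(abs(ours[2] - bci[2]), 0.15 * halfwidth)
})

test_that("BCa approaches the normal-theory interval for a large symmetric sample", {
  set.seed(7)
  x <- rnorm(4000, 10, 2)
  ci <- bca_ci(x, function(d, i) mean(d[i]), B = 3000, seed = 9)
  norm_ci <- mean(x) + qnorm(c(0.025, 0.975)) * sd(x) / sqrt(length(x))
  width <- diff(norm_ci)
  expect_lt(abs(ci[1] - norm_ci[1]), 0.1 * width)
  expect_lt(abs(ci[2] - norm_ci[2]), 0.1 * width)
})

test_that("pooling m identical completed datasets is degenerate", {
  mk_sc <- quick_scenario(n_per_org = 50, seed = 41)
  g <- generate_cohort(mk_sc)
  bd <- client_costs(g$cohort, test_prices())
  bd$model <- g$truth$model_by_client[bd$client_id]
  cmp1 <- compare_care_models(bd, B = 150, seed = 6)
  cmp3 <- compare_care_models(list(bd, bd, bd), B = 150, seed = 6)
  expect_equal(cmp3$contrasts$estimate, cmp1$contrasts$estimate)
  for (p in cmp3$pooled) expect_equal(p$B, 0)
})

test_that("case-mix adjustment removes confounding the raw contrast keeps", {
  sc <- quick_scenario(models = c("CM1", "CM2"), n_per_org = 1500,
                       effects = c(CM1 = 0, CM2 = 2230), seed = 55)
  g <- generate_cohort(sc)
  bd <- client_costs(g$cohort, carecost_prices("dutch_reference"))
  bd$model <- g$truth$model_by_client[bd$client_id]
  f <- fit_adjusted_model(bd, reference = "CM1")
  adj <- unname(coef(f)["modelCM2"])
  raw <- mean(bd$total_societal_6m[bd$model == "CM2"]) -
         mean(bd$total_societal_6m[bd$model == "CM1"])
  # CM2 clients are much less dependent (lower ADLH/CHESS), so the raw
  # difference is biased far below the injected effect
  true_bias <- sum(g$truth$confounding_strength *
                   c(6 * (0.10 - 0.317), 5 * (0.16 - 0.24)))
  se <- sqrt(sum(tapply(bd$total_societal_6m, bd$model, var) /
                 tapply(bd$total_societal_6m, bd$model, length)))
  expect_lt(abs(adj - 2230), 3 * se)
  expect_lt(abs(raw - (2230 + true_bias)), 3 * se)
  expect_gt(abs(raw - 2230), abs(true_bias) / 2)
})

test_that("the comparison object carries reference, methods and manifest", {
  sc <- quick_scenario(models = c("CM1", "CM2", "CM3"), n_per_org = 60,
                       seed = 77)
  g <- generate_cohort(sc)
  bd <- client_costs(g$cohort, test_prices())
  asg <- assign_care_models(g$organizations)
  cmp <- compare_care_models(bd, assignments = asg, B = 120, seed = 2)
  expect_s3_class(cmp, "care_model_comparison")
  expect_identical(sort(cmp$models), c("CM1", "CM2", "CM3"))
  expect_identical(nrow(cmp$contrasts), 3L)  # all pairwise contrasts
  expect_true(all(cmp$contrasts$ci_low <= cmp$contrasts$ci_high))
  expect_identical(names(coef(cmp)), cmp$contrasts$contrast)
  ci <- confint(cmp)
  expect_identical(dim(ci), c(3L, 2L))
  expect_error(confint(cmp, level = 0.9), "refit")
  expect_output(print(summary(cmp)), "Rubin pooling")
  # reference is the lowest unadjusted-cost model
  means <- tapply(bd$total_societal_6m,
                  asg$model[match(bd$org_id, asg$org_id)], mean)
  expect_identical(cmp$reference, names(means)[which.min(means)])
})
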