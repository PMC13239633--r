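test_that("group comparison reports stroke minus control with degenerate variance handled", {
  x <- c(1.2, 1.9, 2.4, 3.0)
  g <- rep(c("stroke", "control"), each = 4)
  same <- group_compare(c(x, x), g)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  # groups rebuilt from printed summary means: 2.20 vs 3.41 -> -1.21
  gc <- group_compare(c(vector_with_mean(10, 2.20), vector_with_mean(10, 3.41)),
                      rep(c("stroke", "control"), each = 10))
  expect_equal(gc$difference, -1.21, tolerance = 1e-10)
  expect_lt(gc$conf_int[1], -1.21); expect_gt(gc$conf_int[2], -1.21)

  deg <- group_compare(c(0, 0, 1, 1), rep(c("stroke", "control"), each = 2))
  expect_equal(deg$difference, -1)
  expect_equal(deg$p_value, 0)

  w <- group_compare(c(x, 10 * x), g, var_equal = FALSE)
  expect_lt(w$df, 6)                     # Welch df < pooled df
  expect_error(group_compare(c(1, 2, 3), c("stroke", "control", "control")),
               "at least 2")
})

test_that("OLS matches the normal-equations oracle and is permutation invariant", {
  y <- c(1.1, 1.9, 3.2, 3.9, 5.1)
  X <- data.frame(x1 = c(1, 2, 3, 4, 5), x2 = c(0.3, -0.1, 0.4, 0.0, 0.2))
  fit <- fit_linear(y, X)
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)   # brute-force normal equations
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  expect_equal(fit$df_residual, 2L)
  expect_equal(fit$p, 3L)

  perm <- c(4, 1, 5, 2, 3)
  fitp <- fit_linear(y[perm], X[perm, ])
  expect_equal(fitp$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(fitp$r_squared, fit$r_squared, tolerance = 1e-12)

  exact <- fit_linear(2 * (1:6), data.frame(x = 1:6))
  expect_equal(exact$coefficients$estimate, c(0, 2), tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)
  expect_lt(exact$sigma, 1e-10)

  expect_error(fit_linear(y, data.frame(a = 1:5, b = 2 * (1:5))),
               "collinear.*b")
  expect_error(fit_linear(1:3, data.frame(a = 1:3, b = c(1, 0, 1))), "n >")
})

test_that("change-in-estimate rule: orthogonal covariates give zero shrinkage and the threshold is strict", {
  x <- rep(c(-1, -1, 1, 1), 3)
  cv <- rep(c(-1, 1, -1, 1), 3)           # orthogonal to x and the intercept
  set.seed(11)
  y <- 2 + 1.5 * x + stats::rnorm(12, 0, 0.4)
  ca <- assess_confounding(y, x, cv)
  expect_equal(ca$adjusted_coef, ca$unadjusted_coef, tolerance = 1e-12)
  expect_equal(ca$shrinkage_fraction, 0, tolerance = 1e-12)
  expect_false(ca$confounded)

  # boundary: shrinkage equal to the threshold is NOT confounding
  set.seed(3)
  x2 <- stats::rnorm(30); cv2 <- 0.7 * x2 + stats::rnorm(30)
  y2 <- 1 + x2 + 0.8 * cv2 + stats::rnorm(30, 0, 0.3)
  ca2 <- assess_confounding(y2, x2, cv2)
  at_boundary <- assess_confounding(y2, x2, cv2,
                                    threshold = ca2$shrinkage_fraction)
  expect_false(at_boundary$confounded)
  below <- assess_confounding(y2, x2, cv2,
                              threshold = ca2$shrinkage_fraction - 1e-9)
  expect_true(below$confounded)

  # outcome orthogonal to exposure: unadjusted coefficient exactly zero
  y0 <- cv                                 # depends only on the covariate
  expect_error(assess_confounding(y0, x, cv), "numerically zero")
})

test_that("a planted confounded-null cohort shows near-total shrinkage", {
  p <- cohort_params(n_pairs = 100, beta_direct = 0, walk_noise_sd_m = 0,
                     seed = 17)
  tab <- make_tabular_cohort(p)
  ca <- assess_confounding(tab$six_mwd_m, tab$ccrst_z, tab$icm_z)
  expect_lt(ca$unadjusted_coef, 0)
  expect_gt(ca$shrinkage_fraction, 0.9)
  expect_true(ca$confounded)
  expect_lt(abs(ca$adjusted_coef), 0.1 * abs(ca$unadjusted_coef))
})

test_that("Cook's distances match the leave-one-out refit oracle and use the median-F threshold", {
  set.seed(23)
  n <- 10
  X <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  y <- 1 + 0.5 * X$x1 - X$x2 + stats::rnorm(n, 0, 0.7)
  fit <- fit_linear(y, X)

  # oracle: D_i = (beta - beta_(i))' X'X (beta - beta_(i)) / (p * s^2)
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  s2 <- sum((y - Xm %*% beta)^2) / (n - 3)
  d_oracle <- sapply(1:n, function(i) {
    bi <- solve(t(Xm[-i, ]) %*% Xm[-i, ], t(Xm[-i, ]) %*% y[-i])
    t(beta - bi) %*% (t(Xm) %*% Xm) %*% (beta - bi) / (3 * s2)
  })
  rep <- cooks_influence(fit)
  expect_equal(unname(rep$cooks_distance), d_oracle, tolerance = 1e-8)
  expect_equal(rep$threshold, stats::qf(0.5, 3, 7))

  # two-predictor model at n = 20: the classic 0.821 threshold
  X20 <- data.frame(a = stats::rnorm(20), b = stats::rnorm(20))
  rep20 <- cooks_influence(fit_linear(stats::rnorm(20), X20))
  expect_equal(round(rep20$threshold, 3), 0.821)

  # perfectly balanced design with equal |residual|: all distances equal
  xb <- rep(c(-1, 1), each = 4)
  yb <- xb + rep(c(-0.3, 0.3), 4)
  db <- cooks_influence(fit_linear(yb, data.frame(x = xb)))$cooks_distance
  expect_equal(max(db) - min(db), 0, tolerance = 1e-12)

  # leverage-one observation: distance undefined
  expect_error(cooks_influence(fit_linear(c(1, 2, 3, 9),
                                          data.frame(x = c(0, 0, 0, 1)))),
               "leverage 1")
})

test_that("leave-one-out refits: on-plane points change nothing, gross outliers vanish", {
  set.seed(5)
  X9 <- data.frame(x1 = stats::rnorm(9), x2 = stats::rnorm(9))
  y9 <- 2 + X9$x1 + 0.5 * X9$x2 + stats::rnorm(9, 0, 0.5)
  f9 <- fit_linear(y9, X9)
  # append a 10th point lying exactly on the 9-point fitted plane
  xn <- c(0.4, -0.2)
  yn <- sum(f9$coefficients$estimate * c(1, xn))
  X10 <- rbind(X9, xn); y10 <- c(y9, yn)
  tab <- loo_sensitivity(y10, X10, drop_id = 10)
  expect_equal(tab$change, rep(0, 3), tolerance = 1e-10)
  expect_equal(tab$full, f9$coefficients$estimate, tolerance = 1e-10)

  # gross outlier: post-drop slope equals OLS on the clean points
  xo <- 1:10
  yo <- 2 * xo; yo[10] <- 60
  tab2 <- loo_sensitivity(yo, data.frame(x = xo), drop_id = 10)
  expect_equal(tab2$dropped, c(0, 2), tolerance = 1e-10)
  expect_gt(abs(tab2$change[2]), 0.5)

  expect_error(loo_sensitivity(yo, data.frame(x = xo), drop_id = "nope"),
               "not found")
})

test_that("minimum detectable effects reproduce the design targets and shrink with n", {
  expect_equal(round(min_detectable_effect("between_t", 10), 2), 1.32)
  expect_equal(round(min_detectable_effect("within_t", 10), 2), 1.00)
  expect_equal(round(min_detectable_effect("correlation", 20), 2), 0.58)

  # cross-check the t families against stats::power.t.test root-finding
  expect_equal(min_detectable_effect("between_t", 10),
               stats::power.t.test(n = 10, power = 0.8)$delta,
               tolerance = 1e-4)
  expect_equal(min_detectable_effect("within_t", 10),
               stats::power.t.test(n = 10, power = 0.8,
                                   type = "one.sample")$delta,
               tolerance = 1e-4)

  for (tst in c("between_t", "within_t", "correlation")) {
    e <- sapply(c(8, 12, 20, 40, 80), min_detectable_effect, test = tst)
    expect_true(all(diff(e) < 0))
  }
  expect_error(min_detectable_effect("correlation", 3), "unattainable")
  expect_error(min_detectable_effect("between_t", 2), ">= 3")
})
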