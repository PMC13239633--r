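#' Stroke-versus-control group comparison
#'
#' Independent t-test of a per-participant value between stroke and
#' control groups, reported as the stroke minus control mean difference
#' with a 95% confidence interval. The default is the classic
#' pooled-variance test (numerically identical to the two-group linear
#' model contrast); Welch's correction is available via `var_equal =
#' FALSE`. Degenerate zero-variance data are handled explicitly: equal
#' groups give p = 1, distinct constant groups give p = 0 with a
#' degenerate CI.
#'
#' @param values numeric vector.
#' @param group character/factor with values `"stroke"` and `"control"`.
#' @param var_equal pooled-variance test if `TRUE` (default).
#' @param conf_level confidence level (default 0.95).
#' @return List with `difference` (stroke - control), `conf_int`,
#'   `p_value`, `t`, `df`, and the group means.
#' @export
group_compare <- function(values, group, var_equal = TRUE, conf_level = 0.95) {
  group <- as.character(group)
  s <- values[group == "stroke"]; c0 <- values[group == "control"]
  if (length(s) < 2 || length(c0) < 2)
    stop("both groups need at least 2 observations")
  diff <- mean(s) - mean(c0)
  pooled_var <- ((length(s) - 1) * stats::var(s) +
                   (length(c0) - 1) * stats::var(c0)) /
    (length(s) + length(c0) - 2)
  if (pooled_var <= .Machine$double.eps * max(1, mean(c(s, c0))^2)) {
    p <- if (abs(diff) < sqrt(.Machine$double.eps)) 1 else 0
    return(list(difference = diff, conf_int = c(diff, diff), p_value = p,
                t = if (p == 1) 0 else Inf * sign(diff),
                df = length(s) + length(c0) - 2,
                mean_stroke = mean(s), mean_control = mean(c0)))
  }
  tt <- stats::t.test(s, c0, var.equal = var_equal, conf.level = conf_level)
  list(difference = diff, conf_int = as.numeric(tt$conf.int),
       p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter),
       mean_stroke = mean(s), mean_control = mean(c0))
}

#' Ordinary least squares with full diagnostics
#'
#' Fits `response ~ predictors` (intercept added automatically) by QR
#' decomposition via [stats::lm()], and returns the coefficient table,
#' fit summaries and per-observation influence quantities used by the
#' confounding and stability analyses.
#'
#' @param response numeric vector.
#' @param predictors numeric vector, matrix or data.frame of predictors
#'   (no intercept column; one is added).
#' @param ids optional observation identifiers (default `1:n`).
#' @return An object of class `regression_result`: `coefficients`
#'   (data.frame term/estimate/se/t/p), `sigma` (residual SE), `df_residual`,
#'   `r_squared`, `adj_r_squared`, `f_statistic` (value/df1/df2/p),
#'   `residuals`, `leverage`, `cooks_distance`, `ids`, `n`, `p` (number of
#'   estimated coefficients, intercept included), and the underlying `lm`
#'   fit.
#' @export
fit_linear <- function(response, predictors, ids = NULL) {
  X <- as.data.frame(predictors)
  if (is.null(names(predictors)) && ncol(X) == 1) names(X) <- "x"
  n <- length(response)
  if (nrow(X) != n) stop("response and predictors have different lengths")
  if (is.null(ids)) ids <- seq_len(n)
  if (n <= ncol(X) + 1) stop("need n > number of coefficients")
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < ncol(X) + 1) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop("predictors are rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  dat <- cbind(.y = response, X)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  co <- stats::coef(sm)
  fstat <- sm$fstatistic
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], t = co[, 3], p = co[, 4],
                              row.names = NULL),
    sigma = sm$sigma, df_residual = fit$df.residual,
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    f_statistic = if (is.null(fstat)) NULL else
      list(value = unname(fstat[1]), df1 = unname(fstat[2]),
           df2 = unname(fstat[3]),
           p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    residuals = unname(stats::residuals(fit)),
    leverage = unname(stats::hatvalues(fit)),
    cooks_distance = unname(stats::cooks.distance(fit)),
    ids = ids, n = n, p = length(stats::coef(fit)),
    fit = fit), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, %d coefficients\n", x$n, x$p))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("Residual SE %.4g on %d df; R-squared %.4f (adj %.4f)\n",
              x$sigma, x$df_residual, x$r_squared, x$adj_r_squared))
  if (!is.null(x$f_statistic))
    cat(sprintf("F = %.4g on %g and %g df, p = %.4g\n", x$f_statistic$value,
                x$f_statistic$df1, x$f_statistic$df2, x$f_statistic$p))
  invisible(x)
}

#' Change-in-estimate confounding assessment
#'
#' Fits the unadjusted model `outcome ~ exposure` and the adjusted model
#' `outcome ~ exposure + covariate`, and declares confounding when adding
#' the covariate shrinks the exposure coefficient by strictly more than
#' the threshold fraction (default 10%). Shrinkage is computed on
#' absolute values, `(|b_unadj| - |b_adj|) / |b_unadj|`, so a sign flip
#' that grows the coefficient yields negative shrinkage (reported, not
#' flagged).
#'
#' @param outcome,exposure,covariate numeric vectors of equal length
#'   (n >= 4).
#' @param threshold shrinkage fraction above which confounding is
#'   declared (strict inequality; default 0.10).
#' @param ids optional observation identifiers.
#' @return An object of class `confounding_assessment`: `unadjusted_coef`,
#'   `adjusted_coef`, `shrinkage_fraction`, `threshold`, `confounded`,
#'   plus both `regression_result` fits (`model_unadjusted`,
#'   `model_adjusted`).
#' @export
assess_confounding <- function(outcome, exposure, covariate,
                               threshold = 0.10, ids = NULL) {
  n <- length(outcome)
  if (length(exposure) != n || length(covariate) != n)
    stop("outcome, exposure and covariate must have equal length")
  if (n < 4) stop("need at least 4 observations")
  m10 <- fit_linear(outcome, data.frame(exposure = exposure), ids = ids)
  m11 <- fit_linear(outcome, data.frame(exposure = exposure,
                                        covariate = covariate), ids = ids)
  b_u <- m10$coefficients$estimate[m10$coefficients$term == "exposure"]
  b_a <- m11$coefficients$estimate[m11$coefficients$term == "exposure"]
  tol <- sqrt(.Machine$double.eps) *
    max(1, stats::sd(outcome) / max(stats::sd(exposure), .Machine$double.eps))
  if (abs(b_u) < tol)
    stop("unadjusted exposure coefficient is numerically zero; ",
         "shrinkage fraction undefined")
  shrink <- (abs(b_u) - abs(b_a)) / abs(b_u)
  structure(list(unadjusted_coef = b_u, adjusted_coef = b_a,
                 shrinkage_fraction = shrink, threshold = threshold,
                 confounded = shrink > threshold,
                 model_unadjusted = m10, model_adjusted = m11),
            class = "confounding_assessment")
}

#' @export
print.confounding_assessment <- function(x, ...) {
  cat(sprintf("exposure coefficient: %.4g unadjusted -> %.4g adjusted\n",
              x$unadjusted_coef, x$adjusted_coef))
  cat(sprintf("shrinkage %.1f%% (threshold %.0f%%): %s\n",
              100 * x$shrinkage_fraction, 100 * x$threshold,
              if (x$confounded) "confounded" else "not confounded"))
  invisible(x)
}

#' Cook's distance influence diagnostics
#'
#' Flags observations whose Cook's distance exceeds the median of the
#' F(p, n - p) distribution, where p counts the estimated coefficients
#' including the intercept (for a two-predictor model at n = 20 this
#' gives the threshold qf(0.5, 3, 17) = 0.821). Each flagged observation
#' gets a leave-one-out coefficient table from [loo_sensitivity()].
#'
#' @param fit a `regression_result` from [fit_linear()].
#' @return An object of class `influence_report`: `cooks_distance` (named
#'   by observation id), `threshold`, `flagged` (ids), `loo` (named list
#'   of leave-one-out tables for flagged ids).
#' @export
cooks_influence <- function(fit) {
  stopifnot(inherits(fit, "regression_result"))
  if (any(fit$leverage >= 1 - 1e-12))
    stop("an observation has leverage 1; Cook's distance is undefined")
  p <- fit$p; n <- fit$n
  thr <- stats::qf(0.5, p, n - p)
  d <- stats::setNames(fit$cooks_distance, fit$ids)
  flagged <- fit$ids[d > thr]
  loo <- lapply(stats::setNames(flagged, flagged), function(i) {
    X <- fit$fit$model[, -1, drop = FALSE]
    loo_sensitivity(fit$fit$model[[1]], X, drop_id = i, ids = fit$ids)
  })
  structure(list(cooks_distance = d, threshold = thr, flagged = flagged,
                 loo = loo, p = p, n = n), class = "influence_report")
}

#' @export
print.influence_report <- function(x, ...) {
  cat(sprintf("Cook's distance threshold: median F(%d, %d) = %.3f\n",
              x$p, x$n - x$p, x$threshold))
  cat(sprintf("max Cook's distance %.3f; %d observation(s) flagged%s\n",
              max(x$cooks_distance), length(x$flagged),
              if (length(x$flagged)) paste0(": ", paste(x$flagged, collapse = ", "))
              else ""))
  invisible(x)
}

#' Leave-one-out coefficient sensitivity
#'
#' Refits the model with one observation removed and tabulates the
#' before/after coefficients — the stability probe applied to
#' observations flagged by [cooks_influence()].
#'
#' @param response numeric vector.
#' @param predictors matrix/data.frame of predictors (no intercept).
#' @param drop_id identifier of the observation to drop.
#' @param ids observation identifiers (default `1:n`).
#' @return data.frame with columns `term`, `full`, `dropped`, `change`.
#' @export
loo_sensitivity <- function(response, predictors, drop_id, ids = NULL) {
  X <- as.data.frame(predictors)
  n <- length(response)
  if (is.null(ids)) ids <- seq_len(n)
  j <- which(ids == drop_id)
  if (length(j) != 1L) stop("drop_id not found among observation ids: ",
                            drop_id)
  if (n - 1 <= ncol(X) + 1) stop("too few observations left after dropping")
  full <- fit_linear(response, X, ids = ids)
  red <- fit_linear(response[-j], X[-j, , drop = FALSE], ids = ids[-j])
  data.frame(term = full$coefficients$term,
             full = full$coefficients$estimate,
             dropped = red$coefficients$estimate,
             change = red$coefficients$estimate - full$coefficients$estimate,
             row.names = NULL)
}

#' Minimum detectable effect at a target power
#'
#' Root-finds the effect size at which the two-sided test attains the
#' requested power: exact noncentral-t power for the t-test families, and
#' Fisher-z approximate power with the r/(2(n-1)) small-sample bias
#' correction on the effect size for correlations. With the defaults this
#' reproduces the classic design targets d = 1.32 (two-sample, n = 10 per
#' group), d = 1.00 (one-sample/within, n = 10) and r = 0.58 (total
#' n = 20) at 80% power.
#'
#' @param test `"between_t"` (two-sample; `n` per group), `"within_t"`
#'   (one-sample/paired; `n` pairs) or `"correlation"` (total `n`).
#' @param n sample size (per group where applicable), >= 3.
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return The minimum detectable Cohen's d, or correlation r.
#' @examples
#' min_detectable_effect("between_t", 10)   # 1.32
#' min_detectable_effect("correlation", 20) # 0.58
#' @export
min_detectable_effect <- function(test = c("between_t", "within_t", "correlation"),
                                  n, alpha = 0.05, power = 0.80) {
  test <- match.arg(test)
  if (n < 3) stop("n must be >= 3")
  pw <- switch(test,
    between_t = function(d) {
      df <- 2 * n - 2; ncp <- d * sqrt(n / 2); q <- stats::qt(1 - alpha / 2, df)
      stats::pt(q, df, ncp, lower.tail = FALSE) + stats::pt(-q, df, ncp)
    },
    within_t = function(d) {
      df <- n - 1; ncp <- d * sqrt(n); q <- stats::qt(1 - alpha / 2, df)
      stats::pt(q, df, ncp, lower.tail = FALSE) + stats::pt(-q, df, ncp)
    },
    correlation = function(r) {
      q <- stats::qt(1 - alpha / 2, n - 2)
      rc <- sqrt(q^2 / (q^2 + n - 2))
      stats::pnorm((atanh(r) + r / (2 * (n - 1)) - atanh(rc)) * sqrt(n - 3))
    })
  hi <- if (test == "correlation") 0.999 else 50
  if (pw(hi) < power)
    stop(sprintf("power %.2f unattainable for %s at n = %g", power, test, n))
  stats::uniroot(function(e) pw(e) - power, c(1e-8, hi), tol = 1e-10)$root
}
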