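#' Percentile bootstrap interval for a mean, with inverted p value
#'
#' Resamples the values with replacement `n` times, forms the distribution of
#' resampled means, reports its percentile 95% interval and the two-sided
#' p value obtained by interval inversion: the smallest level at which the
#' percentile interval excludes `baseline`.
#'
#' @param values numeric vector (>= 2 values).
#' @param baseline null value the interval is inverted against.
#' @param n number of bootstrap resamples (default 100000).
#' @param seed integer seed.
#' @param level interval level (default 0.95).
#' @return object of class `bootstrap_result`: `mean`, `bi_low`, `bi_high`,
#'   `p_bootstrap`, `n_resamples`.
#' @export
bootstrap_interval <- function(values, baseline = 0, n = 100000L, seed = 1L,
                               level = 0.95) {
  if (length(values) < 2L) stopf("need at least 2 values")
  boot <- with_seed(seed, {
    m <- matrix(sample(values, n * length(values), replace = TRUE),
                nrow = n)
    rowMeans(m)
  })
  qs <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  p <- 2 * min(mean(boot <= baseline), mean(boot >= baseline))
  p <- min(1, max(p, 1 / n))
  structure(list(mean = mean(values), bi_low = qs[1], bi_high = qs[2],
                 p_bootstrap = p, n_resamples = n, baseline = baseline),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("mean %.4g, 95%% BI [%.4g, %.4g], P_bootstrap %s\n",
              x$mean, x$bi_low, x$bi_high,
              if (x$p_bootstrap <= 1 / x$n_resamples)
                sprintf("< %g", 1 / x$n_resamples)
              else sprintf("= %.4g", x$p_bootstrap)))
  invisible(x)
}

welch_t <- function(x0, x1) {
  se <- sqrt(var(x0) / length(x0) + var(x1) / length(x1))
  dm <- mean(x0) - mean(x1)
  if (se == 0) {
    if (dm == 0) 0 else sign(dm) * Inf
  } else dm / se
}

#' Fisher randomization test with the Welch statistic
#'
#' Tests the sharp null hypothesis that each unit's outcome is unaffected by
#' its group label, by comparing the observed Welch t statistic against its
#' distribution over re-randomized label allocations. All allocations are
#' enumerated exactly when their number does not exceed `n`; otherwise `n`
#' random allocations are drawn and the observed allocation is included
#' (add-one convention), so that p > 0.
#'
#' @param group0,group1 numeric outcome vectors (>= 2 values each).
#' @param sided "two" (default), or one-sided "greater"/"less" for the
#'   alternative that `mean(group0) - mean(group1)` is greater/less than zero.
#' @param n maximum number of randomized allocations (default 100000).
#' @param seed integer seed (used only on the Monte-Carlo path).
#' @return object of class `randomization_result`: `statistic_observed`,
#'   `p_value`, `n_permutations`, `sidedness`, `exact`.
#' @export
randomization_test <- function(group0, group1,
                               sided = c("two", "greater", "less"),
                               n = 100000L, seed = 1L) {
  sided <- match.arg(sided)
  if (length(group0) < 2L || length(group1) < 2L)
    stopf("need at least 2 observations per group")
  pooled <- c(group0, group1)
  n0 <- length(group0)
  N <- length(pooled)
  t_obs <- welch_t(group0, group1)
  n_alloc <- choose(N, n0)
  exact <- n_alloc <= n
  ts <- if (exact) {
    idx <- combn(N, n0)
    apply(idx, 2, function(i) welch_t(pooled[i], pooled[-i]))
  } else {
    with_seed(seed, {
      c(t_obs, vapply(seq_len(n - 1L), function(k) {
        i <- sample.int(N, n0)
        welch_t(pooled[i], pooled[-i])
      }, 1.0))
    })
  }
  eps <- 1e-12
  cmp <- switch(sided,
    two = abs(ts) >= abs(t_obs) - eps,
    greater = ts >= t_obs - eps,
    less = ts <= t_obs + eps)
  # zero-variance degenerate case: all statistics 0 -> p = 1
  p <- mean(cmp)
  structure(list(statistic_observed = t_obs, p_value = p,
                 n_permutations = length(ts), sidedness = sided,
                 exact = exact),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("T_Welch = %.4g, P_Fisher (%s-sided%s) = %.4g  [%d allocations]\n",
              x$statistic_observed, x$sidedness,
              if (x$exact) ", exact" else "", x$p_value, x$n_permutations))
  invisible(x)
}

#' Cohen's d effect size
#'
#' Two-sample form `(mean(x1) - mean(x2)) / S_p` with `S_p` the pooled SD, or
#' one-sample form `(mean(x1) - mu0) / S_1` when `mu0` is given instead of a
#' second sample.
#'
#' @param x1 numeric vector.
#' @param x2 optional second sample.
#' @param mu0 optional null mean for the one-sample form.
#' @return signed effect size (scalar).
#' @export
cohens_d <- function(x1, x2 = NULL, mu0 = NULL) {
  if (is.null(x2) == is.null(mu0))
    stopf("supply exactly one of x2 (two-sample) or mu0 (one-sample)")
  if (!is.null(x2)) {
    n1 <- length(x1); n2 <- length(x2)
    sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
    if (sp == 0) {
      if (mean(x1) == mean(x2)) return(0)
      stopf("zero pooled SD with unequal means")
    }
    (mean(x1) - mean(x2)) / sp
  } else {
    s1 <- sd(x1)
    if (s1 == 0) {
      if (mean(x1) == mu0) return(0)
      stopf("zero SD with mean differing from mu0")
    }
    (mean(x1) - mu0) / s1
  }
}

#' Linear regression with pointwise 95% CI band
#'
#' Ordinary least squares fit of y on x with the pointwise confidence band
#' `yhat_i +/- t(0.95, n-2) * S_est * sqrt(1/n + (x_i - xbar)^2 / sum (x - xbar)^2)`,
#' where `S_est` is the residual standard deviation, plus Pearson's r.
#'
#' @param x,y numeric vectors (n >= 3; x not constant).
#' @return object of class `regression_ci`: `slope`, `intercept`, `r`,
#'   `s_est`, and `band` (data frame `x`, `fit`, `lo`, `hi`, sorted by x).
#' @export
regression_ci <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stopf("need n >= 3")
  if (sd(x) == 0) stopf("x is constant")
  fit <- lm(y ~ x)
  yhat <- fitted(fit)
  s_est <- sqrt(sum(residuals(fit)^2) / (n - 2))
  tq <- qt(0.975, n - 2)
  half <- tq * s_est * sqrt(1 / n + (x - mean(x))^2 / sum((x - mean(x))^2))
  ord <- order(x)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r = if (sd(y) == 0) NA_real_ else unname(cor(x, y)),
                 s_est = s_est,
                 band = data.frame(x = x[ord], fit = yhat[ord],
                                   lo = (yhat - half)[ord],
                                   hi = (yhat + half)[ord])),
            class = "regression_ci")
}

#' @export
print.regression_ci <- function(x, ...) {
  cat(sprintf("slope %.4g, intercept %.4g, r_Pearson %.3f, S_est %.4g\n",
              x$slope, x$intercept, x$r, x$s_est))
  invisible(x)
}
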