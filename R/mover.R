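# Closed-form MOVER interval: the log-mean splits as
# theta = log(1 - delta) + log(a + exp(mu + sigma2/2)) = log(theta1) + log(theta2),
# and component intervals are combined by variance-estimate recovery.

# Generic recovery combination of two component intervals around a sum of
# point estimates: distances to each limit are recovered and added in
# quadrature.
mover_combine <- function(est1, l1, u1, est2, l2, u2) {
  c(lower = (est1 + est2) - sqrt((est1 - l1)^2 + (est2 - l2)^2),
    upper = (est1 + est2) + sqrt((u1 - est1)^2 + (u2 - est2)^2))
}

#' Wilson interval for the log survival proportion
#'
#' Wilson score interval for the proportion of positive observations
#' `theta1 = 1 - delta`, reported on the log scale:
#' `log[(n1 + k^2/2 -+ k sqrt(n0 n1 / n + k^2/4)) / (n + k^2)]` with `k` the
#' upper `alpha/2` standard-normal quantile. Both bounds are `<= 0` and the
#' interval always contains `log(n1/n)`.
#'
#' @param n0 number of zeros.
#' @param n1 number of positive observations (`>= 1`).
#' @param level confidence level (default 0.95).
#' @return A `"dtpln_interval"` for `log(1 - delta)`.
#' @export
wilson_log_interval <- function(n0, n1, level = 0.95) {
  stopifnot(n0 >= 0, n1 >= 1)
  n <- n0 + n1
  k <- stats::qnorm(1 - (1 - level) / 2)
  centre <- n1 + k^2 / 2
  half <- k * sqrt(n0 * n1 / n + k^2 / 4)
  denom <- n + k^2
  new_interval(log((centre - half) / denom), log((centre + half) / denom),
               level, "Wilson (log scale)")
}

#' Asymptotic confidence interval for the threshold
#'
#' `a_hat -+ t_{alpha/2, n1-2} * sqrt(var_a_hat)`, with `t` the upper-tail
#' Student-t quantile so the lower bound is below the upper. Symmetric about
#' `a_hat`; it may extend below zero, which is harmless because it is used
#' only as a component distance inside the MOVER combination.
#'
#' @param a_hat threshold estimate.
#' @param var_a_hat its asymptotic variance ([threshold_variance()]).
#' @param n1 number of positive observations (`>= 3`).
#' @param level confidence level (default 0.95).
#' @return A `"dtpln_interval"` for the threshold.
#' @export
threshold_interval <- function(a_hat, var_a_hat, n1, level = 0.95) {
  stopifnot(var_a_hat >= 0, n1 >= 3)
  tq <- stats::qt(1 - (1 - level) / 2, df = n1 - 2)
  h <- tq * sqrt(var_a_hat)
  new_interval(a_hat - h, a_hat + h, level, "threshold", scale = "original")
}

#' Confidence interval for the lognormal log-mean `mu + sigma2/2`
#'
#' The variance-recovery interval for the log of a lognormal mean:
#' `mu_hat + s2/2 -+ sqrt(w^2_{alpha/2} s2/n1 + (s2^2/2) (1 - (n1 - 1)/
#' chi^2_{q, n1-1})^2)` with `q = 1 - alpha/2` for the lower bound and
#' `q = alpha/2` for the upper. The upper half-width always exceeds the lower
#' one, reflecting the right skew of the variance component.
#'
#' @param mu_hat log-scale location estimate.
#' @param s2 unbiased log-scale variance estimate (`> 0`).
#' @param n1 number of positive observations (`>= 2`).
#' @param level confidence level (default 0.95).
#' @return A `"dtpln_interval"` for `mu + sigma2/2`.
#' @export
meanlog_interval <- function(mu_hat, s2, n1, level = 0.95) {
  stopifnot(s2 > 0, n1 >= 2)
  alpha <- 1 - level
  w <- stats::qnorm(1 - alpha / 2)
  point <- mu_hat + s2 / 2
  half <- function(q)
    sqrt(w^2 * s2 / n1 +
           (s2^2 / 2) * (1 - (n1 - 1) / stats::qchisq(q, n1 - 1))^2)
  new_interval(point - half(1 - alpha / 2), point + half(alpha / 2),
               level, "meanlog")
}

#' MOVER interval for the DTPLN log-mean
#'
#' Deterministic closed-form interval: the Wilson interval for
#' `log(theta1) = log(1 - delta)` is combined with a recovered interval for
#' `log(theta2) = log(a + exp(mu + sigma2/2))`, itself built by combining the
#' threshold interval with the `mu + sigma2/2` interval inside `theta2_hat`.
#'
#' The inner combination mixes a quantity in data units (`a`) with one on the
#' log scale (`mu + sigma2/2`); with the default
#' `component2_scale = "original"` the second distance is measured between
#' `exp(mu_hat + s2/2)` and the exponentiated `mu + sigma2/2` limits, which is
#' dimensionally consistent with `a + exp(...)`. `"log"` uses the log-scale
#' distances literally.
#'
#' @param fit a [dtpln_fit()] object (or a sample, which will be fitted).
#' @param level confidence level (default 0.95).
#' @param component2_scale `"original"` (default) or `"log"`; see Details.
#' @return A `"dtpln_interval"` for `theta`. Errors (rather than clamping) if
#'   the recovered lower distance reaches `theta2_hat`, which would make the
#'   inner logarithm nonpositive.
#' @export
mover_interval <- function(fit, level = 0.95,
                           component2_scale = c("original", "log")) {
  component2_scale <- match.arg(component2_scale)
  if (!inherits(fit, "dtpln_fit")) fit <- dtpln_fit(fit)
  stopifnot(fit$n1 >= 3)
  theta1_hat <- 1 - fit$delta_hat
  ml <- fit$mu_hat + fit$s2_unbiased / 2
  e_ml <- exp(ml)
  theta2_hat <- fit$a_hat + e_ml
  wi <- wilson_log_interval(fit$n0, fit$n1, level)
  ai <- threshold_interval(fit$a_hat, fit$var_a_hat, fit$n1, level)
  mi <- meanlog_interval(fit$mu_hat, fit$s2_unbiased, fit$n1, level)
  if (component2_scale == "original") {
    d_lo <- sqrt((fit$a_hat - ai$lower)^2 + (e_ml - exp(mi$lower))^2)
    d_up <- sqrt((ai$upper - fit$a_hat)^2 + (exp(mi$upper) - e_ml)^2)
  } else {
    d_lo <- sqrt((fit$a_hat - ai$lower)^2 + (ml - mi$lower)^2)
    d_up <- sqrt((ai$upper - fit$a_hat)^2 + (mi$upper - ml)^2)
  }
  if (theta2_hat - d_lo <= 0)
    stop("MOVER inner lower distance reaches theta2_hat; log undefined")
  l2 <- log(theta2_hat - d_lo)
  u2 <- log(theta2_hat + d_up)
  out <- mover_combine(log(theta1_hat), wi$lower, wi$upper,
                       log(theta2_hat), l2, u2)
  new_interval(out[["lower"]], out[["upper"]], level, "MOVER")
}
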