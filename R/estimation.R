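# Point estimation: MLEs of delta, mu, sigma2 given the threshold, the
# Cohen-Whitten modified-moment threshold estimate, and its asymptotic variance.

.dtpln_cache <- new.env(parent = emptyenv())

# Expectation of the smallest order statistic of n iid standard normals,
# by numeric integration; cached per n (needed once per sample size).
expected_min_zscore <- function(n) {
  key <- as.character(n)
  if (!is.null(.dtpln_cache[[key]])) return(.dtpln_cache[[key]])
  f <- function(z) n * z * stats::dnorm(z) * (1 - stats::pnorm(z))^(n - 1)
  v <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-12)$value
  .dtpln_cache[[key]] <- v
  v
}

# Expected minimum of n iid lognormal(mu, sigma) variables (raw-scale variant).
expected_min_lognormal <- function(mu, sigma, n) {
  f <- function(z) n * exp(mu + sigma * z) *
    stats::dnorm(z) * (1 - stats::pnorm(z))^(n - 1)
  # integrand decays like exp(-n z^2 /2) on the right; [-12, 12] is exhaustive
  stats::integrate(f, -12, 12, rel.tol = 1e-10)$value
}

#' Zero-proportion estimate
#'
#' Maximum likelihood estimate of the zero probability: `n0 / n`.
#'
#' @param n0 number of exact zeros.
#' @param n total sample size.
#' @export
estimate_delta <- function(n0, n) {
  stopifnot(n >= 1, n0 >= 0, n0 <= n)
  n0 / n
}

# Profile (mu, sigma2) out of the moment system at a candidate threshold:
# match the sample mean to a + exp(mu + sigma2/2) and the (unbiased) sample
# variance to exp(2 mu + sigma2) (exp(sigma2) - 1).
.profile_moments <- function(a, xbar, v) {
  M <- xbar - a
  s2 <- log1p(v / M^2)
  c(mu = log(M) - s2 / 2, s2 = s2)
}

#' Modified-moment threshold estimate
#'
#' Cohen-Whitten modified method of moments for the threshold of a
#' three-parameter lognormal sample: with `mu` and `sigma2` profiled out by
#' matching the sample mean and (unbiased) sample variance, the threshold is
#' the root in `[0, min(positives))` of the third matching equation. The
#' default `"log"` variant matches the smallest observation on the log scale,
#' `ln(x_(1) - a) = mu + sigma * E[z_(1:n1)]` with `z_(1:n1)` the smallest of
#' `n1` standard normal order statistics; the `"raw"` variant matches `x_(1)`
#' to the expected minimum of the fitted shifted lognormal itself.
#'
#' @param positives vector of positive observations (`n1 >= 3`).
#' @param variant `"log"` (default) or `"raw"`; see Details.
#' @param fallback_zero if `TRUE` (default), return 0 with a warning when the
#'   moment residual has no sign change on the search interval (a small-sample
#'   pathology met occasionally in simulation); if `FALSE`, error instead.
#' @return The threshold estimate, with attribute `"converged"` (logical).
#' @export
#' @examples
#' x <- rainfall_fixture()
#' estimate_threshold(x$positives) # 1.7604
estimate_threshold <- function(positives,
                               variant = c("log", "raw"),
                               fallback_zero = TRUE) {
  variant <- match.arg(variant)
  n1 <- length(positives)
  stopifnot(n1 >= 3, all(positives > 0))
  xbar <- mean(positives)
  v <- stats::var(positives)
  x1 <- min(positives)
  if (v <= 0) stop("positive observations are all equal; threshold undefined")
  ez1 <- expected_min_zscore(n1)
  resid <- function(a) {
    th <- .profile_moments(a, xbar, v)
    if (variant == "log") {
      log(x1 - a) - (th[["mu"]] + sqrt(th[["s2"]]) * ez1)
    } else {
      x1 - (a + expected_min_lognormal(th[["mu"]], sqrt(th[["s2"]]), n1))
    }
  }
  hi <- x1 * (1 - 1e-9)
  r_lo <- resid(0)
  r_hi <- resid(hi)
  if (!is.finite(r_lo) || !is.finite(r_hi) || r_lo * r_hi > 0) {
    msg <- sprintf(
      "no sign change of the moment residual on [0, %.6g] (f(0) = %.4g, f(hi) = %.4g)",
      hi, r_lo, r_hi)
    if (!fallback_zero) stop(msg)
    warning("threshold estimate fell back to 0: ", msg)
    return(structure(0, converged = FALSE))
  }
  root <- stats::uniroot(resid, c(0, hi), tol = 1e-12)$root
  # polish so the residual itself is within tolerance, not just the bracket
  structure(root, converged = TRUE)
}

#' Likelihood score for the threshold
#'
#' Evaluates the partial derivative of the DTPLN log-likelihood with respect to
#' the threshold at a candidate value, `sum(1/(x - a)) +
#' sum((ln(x - a) - mu)/(sigma2 * (x - a)))`. When `mu`/`sigma2` are omitted
#' they are profiled at their MLEs given `a` (divisor `n1`), so the value is
#' also the derivative of the profile log-likelihood (envelope identity). A
#' consistent root lies near the likelihood threshold estimate; this is a
#' diagnostic, not the default estimator.
#'
#' @param a candidate threshold, `< min(positives)`.
#' @param positives vector of positive observations.
#' @param mu,sigma2 optional fixed log-scale location and variance.
#' @return The score value (a single number).
#' @export
threshold_score <- function(a, positives, mu = NULL, sigma2 = NULL) {
  stopifnot(length(a) == 1L, all(positives > 0))
  if (a >= min(positives))
    stop("'a' must be strictly below the smallest positive observation")
  lg <- log(positives - a)
  if (is.null(mu) || is.null(sigma2)) {
    mu <- mean(lg)
    sigma2 <- mean((lg - mu)^2)
  }
  sum(1 / (positives - a)) + sum((lg - mu) / (positives - a)) / sigma2
}

#' Log-scale location and variance given the threshold
#'
#' Mean and dispersion of `ln(x - a)` over the positive observations. The
#' `"unbiased"` divisor (`n1 - 1`) is what every interval method consumes; the
#' `"mle"` divisor (`n1`) maximizes the likelihood at fixed `a`.
#'
#' @param positives vector of positive observations (`n1 >= 2`).
#' @param a threshold, strictly below every positive value.
#' @param divisor `"unbiased"` (default) or `"mle"`.
#' @return `list(mu, s2)`.
#' @export
estimate_location_scale <- function(positives, a,
                                    divisor = c("unbiased", "mle")) {
  divisor <- match.arg(divisor)
  n1 <- length(positives)
  stopifnot(n1 >= 2)
  if (any(positives <= a))
    stop("every positive observation must exceed the threshold 'a'")
  lg <- log(positives - a)
  mu <- mean(lg)
  ss <- sum((lg - mu)^2)
  list(mu = mu, s2 = ss / if (divisor == "unbiased") n1 - 1 else n1)
}

#' Asymptotic variance of the threshold estimate
#'
#' Fisher-information-based variance of the threshold estimator,
#' `sigma2 * exp(2 mu - sigma2) / (n1 * (exp(sigma2) * (1 + sigma2) -
#' 2 sigma2 - 1))`, evaluated at the plug-in estimates. Strictly positive and
#' proportional to `1/n1`.
#'
#' @param mu,s2 log-scale location and variance estimates (`s2 > 0`).
#' @param n1 number of positive observations (`>= 3`).
#' @export
threshold_variance <- function(mu, s2, n1) {
  stopifnot(s2 > 0, n1 >= 3)
  denom <- exp(s2) * (1 + s2) - 2 * s2 - 1
  # denom = sum_{k>=2} s2^k (k-1)/k! > 0 for every s2 > 0
  stopifnot(denom > 0)
  s2 * exp(2 * mu - s2) / (n1 * denom)
}

#' DTPLN log-likelihood
#'
#' Log-likelihood of a DTPLN parameter set on a sample, omitting the binomial
#' coefficient term (which depends on the data only). The normal-density
#' constant `-n1/2 * log(2 pi)` *is* included, so the value equals the sum of
#' per-observation log densities: `n0 log(delta)` for the zeros plus
#' `log((1 - delta) * tpln_pdf(x))` for the positives.
#'
#' @param params a [dtpln_params()] object.
#' @param sample a [sample_data()] object (or numeric vector).
#' @return The log-likelihood; `-Inf` (not an error) when the threshold is at
#'   or above the smallest positive observation, or when `delta` is 0 with
#'   zeros present.
#' @export
dtpln_loglik <- function(params, sample) {
  stopifnot(inherits(params, "dtpln_params"))
  sample <- as_sample(sample)
  p <- sample$positives
  if (sample$n1 > 0 && params$a >= sample$min_pos) return(-Inf)
  if (sample$n0 > 0 && params$delta == 0) return(-Inf)
  ll <- 0
  if (sample$n0 > 0) ll <- ll + sample$n0 * log(params$delta)
  if (sample$n1 > 0) {
    lg <- log(p - params$a)
    ll <- ll + sample$n1 * log1p(-params$delta) -
      sample$n1 / 2 * log(2 * pi * params$sigma2) -
      sum((lg - params$mu)^2) / (2 * params$sigma2) - sum(lg)
  }
  ll
}

#' Fit the DTPLN model to a sample
#'
#' The single entry point used by every interval method: composes the
#' zero-proportion MLE, the modified-moment threshold estimate, the log-scale
#' location/variance estimates under both divisors, and the asymptotic
#' threshold variance.
#'
#' @param sample a [sample_data()] object or numeric vector of nonnegative
#'   values; needs at least 3 positives.
#' @param variant threshold estimator variant, see [estimate_threshold()].
#' @return An object of class `"dtpln_fit"`: a list with `delta_hat`, `a_hat`,
#'   `mu_hat`, `s2_unbiased`, `s2_mle`, `var_a_hat`, `n`, `n0`, `n1`,
#'   `min_pos`, `mean_pos` (arithmetic mean of the positives), `theta_hat`
#'   (estimated log-mean, using the unbiased variance), `mean_hat =
#'   exp(theta_hat)`, and `threshold_converged`.
#' @export
#' @examples
#' fit <- dtpln_fit(rainfall_fixture())
#' fit
dtpln_fit <- function(sample, variant = c("log", "raw")) {
  sample <- as_sample(sample)
  stopifnot(sample$n1 >= 3)
  variant <- match.arg(variant)
  a_hat <- estimate_threshold(sample$positives, variant = variant)
  conv <- isTRUE(attr(a_hat, "converged"))
  a_hat <- as.numeric(a_hat)
  stopifnot(a_hat < sample$min_pos)
  unb <- estimate_location_scale(sample$positives, a_hat, "unbiased")
  delta_hat <- estimate_delta(sample$n0, sample$n)
  theta_hat <- log1p(-delta_hat) +
    log(a_hat + exp(unb$mu + unb$s2 / 2))
  structure(list(
    delta_hat = delta_hat,
    a_hat = a_hat,
    mu_hat = unb$mu,
    s2_unbiased = unb$s2,
    s2_mle = unb$s2 * (sample$n1 - 1) / sample$n1,
    var_a_hat = threshold_variance(unb$mu, unb$s2, sample$n1),
    n = sample$n, n0 = sample$n0, n1 = sample$n1,
    min_pos = sample$min_pos,
    mean_pos = mean(sample$positives),
    theta_hat = theta_hat,
    mean_hat = exp(theta_hat),
    threshold_converged = conv,
    sample = sample
  ), class = "dtpln_fit")
}

#' @export
print.dtpln_fit <- function(x, ...) {
  cat("DTPLN fit\n")
  cat(sprintf("  n = %d (n0 = %d zeros, n1 = %d positive)\n", x$n, x$n0, x$n1))
  cat(sprintf("  delta_hat = %.4f   a_hat = %.4f%s\n",
              x$delta_hat, x$a_hat,
              if (x$threshold_converged) "" else " (fallback, no root)"))
  cat(sprintf("  mu_hat = %.4f   s2 = %.4f (unbiased) / %.4f (mle)\n",
              x$mu_hat, x$s2_unbiased, x$s2_mle))
  cat(sprintf("  var(a_hat) = %.4f\n", x$var_a_hat))
  cat(sprintf("  theta_hat = %.4f   mean = exp(theta_hat) = %.4f\n",
              x$theta_hat, x$mean_hat))
  invisible(x)
}
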