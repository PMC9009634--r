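#' DTPLN parameter set
#'
#' Bundles the four parameters of the delta-three-parameter lognormal (DTPLN)
#' model: an observation is exactly zero with probability `delta`, otherwise it
#' equals `a + exp(Y)` with `Y ~ N(mu, sigma2)`. The threshold `a` is the lower
#' bound of the positive support and has the same units as the data (mm/wk for
#' rainfall); `mu` and `sigma2` are on the log scale.
#'
#' @param delta probability of a zero observation, in `[0, 1)`. `delta = 0`
#'   gives the pure three-parameter lognormal; `delta = 1` is rejected because
#'   the mean (and hence its logarithm) is then undefined.
#' @param mu log-scale location of the positive part.
#' @param sigma2 log-scale variance of the positive part, `> 0`.
#' @param a threshold (lower bound of the positive support), `>= 0`.
#'
#' @return An object of class `"dtpln_params"`.
#' @seealso [dtpln_theta()], [rdtpln()], [dtpln_cdf()]
#' @export
#' @examples
#' p <- dtpln_params(delta = 0.1, mu = 2, sigma2 = 0.5, a = 5)
#' dtpln_theta(p)
dtpln_params <- function(delta, mu, sigma2, a) {
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma2), length(sigma2) == 1L, is.finite(sigma2),
            is.numeric(a), length(a) == 1L, is.finite(a))
  if (delta < 0 || delta >= 1)
    stop("'delta' must lie in [0, 1): the log-mean is undefined at delta = 1")
  if (sigma2 <= 0) stop("'sigma2' must be > 0")
  if (a < 0) stop("'a' must be >= 0")
  structure(list(delta = delta, mu = mu, sigma2 = sigma2, a = a),
            class = "dtpln_params")
}

#' @export
print.dtpln_params <- function(x, ...) {
  cat(sprintf("DTPLN(delta = %g, mu = %g, sigma2 = %g, a = %g)\n",
              x$delta, x$mu, x$sigma2, x$a))
  cat(sprintf("  log-mean theta = %.6g, mean = %.6g\n",
              dtpln_theta(x), dtpln_mean(x)))
  invisible(x)
}

#' Log-transformed mean of a DTPLN distribution
#'
#' The distribution mean is `(1 - delta) * (a + exp(mu + sigma2/2))`; all
#' interval methods in this package target its natural logarithm
#' `theta = log(1 - delta) + log(a + exp(mu + sigma2/2))`.
#'
#' @param params a [dtpln_params()] object.
#' @return The log-mean `theta` (a single number); `exp(dtpln_theta(p))` is the
#'   distribution mean on the original scale.
#' @export
dtpln_theta <- function(params) {
  stopifnot(inherits(params, "dtpln_params"))
  log1p(-params$delta) + log(params$a + exp(params$mu + params$sigma2 / 2))
}

#' @rdname dtpln_theta
#' @export
dtpln_mean <- function(params) exp(dtpln_theta(params))

#' DTPLN cumulative distribution function
#'
#' Point mass `delta` at zero, no mass on `(0, a]`, and the shifted-lognormal
#' distribution on `(a, Inf)`.
#'
#' @param x vector of nonnegative quantiles.
#' @param params a [dtpln_params()] object.
#' @return `P(X <= x)`, vectorized over `x`.
#' @export
dtpln_cdf <- function(x, params) {
  stopifnot(inherits(params, "dtpln_params"), is.numeric(x))
  out <- numeric(length(x))
  out[x < 0] <- 0
  mid <- x >= 0 & x <= params$a
  out[mid] <- params$delta
  hi <- x > params$a
  out[hi] <- params$delta +
    (1 - params$delta) * stats::plnorm(x[hi] - params$a,
                                       meanlog = params$mu,
                                       sdlog = sqrt(params$sigma2))
  out
}

#' Density of the positive (three-parameter lognormal) part
#'
#' Density of `X = a + exp(Y)`, `Y ~ N(mu, sigma2)`, defined on `x > a`.
#' Values at or below the threshold are a domain error: the positive part of a
#' DTPLN sample cannot reach the threshold.
#'
#' @inheritParams dtpln_cdf
#' @return Density values, vectorized over `x`.
#' @export
tpln_pdf <- function(x, params) {
  stopifnot(inherits(params, "dtpln_params"), is.numeric(x))
  if (any(x <= params$a))
    stop("'x' must be strictly greater than the threshold 'a'")
  stats::dlnorm(x - params$a, meanlog = params$mu, sdlog = sqrt(params$sigma2))
}

#' Draw a DTPLN random sample
#'
#' Each observation is zero with probability `delta`, otherwise
#' `a + exp(N(mu, sigma2))`. Fully reproducible for a fixed `seed`.
#'
#' @param n sample size.
#' @param params a [dtpln_params()] object.
#' @param seed optional integer seed; if supplied, `set.seed(seed)` is called
#'   before drawing.
#' @return A [sample_data()] object holding the `n` values.
#' @export
#' @examples
#' s <- rdtpln(100, dtpln_params(0.3, 2, 0.5, 5), seed = 1)
#' s$n0 / s$n
rdtpln <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "dtpln_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  zero <- stats::rbinom(n, 1L, params$delta) == 1L
  x <- numeric(n)
  npos <- sum(!zero)
  if (npos > 0)
    x[!zero] <- params$a +
      exp(stats::rnorm(npos, params$mu, sqrt(params$sigma2)))
  sample_data(x)
}

#' Observed sample container
#'
#' Wraps a vector of nonnegative observations and precomputes the zero/positive
#' partition used throughout estimation. Zeros are detected by exact equality
#' with 0; values in `(0, a]` are legal under the model CDF but are rejected by
#' the estimation routines because they indicate a misspecified threshold.
#'
#' @param values numeric vector of nonnegative values (zeros meaningful).
#' @return An object of class `"dtpln_sample"` with fields `values`, `n`,
#'   `n0` (zero count), `n1` (positive count), `positives`, and `min_pos`
#'   (smallest positive value, `NA` when there is none).
#' @export
sample_data <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (any(!is.finite(values))) stop("all values must be finite")
  if (any(values < 0)) stop("all values must be nonnegative")
  values <- as.numeric(values)
  pos <- values[values > 0]
  structure(list(values = values,
                 n = length(values),
                 n0 = sum(values == 0),
                 n1 = length(pos),
                 positives = pos,
                 min_pos = if (length(pos)) min(pos) else NA_real_),
            class = "dtpln_sample")
}

#' @export
print.dtpln_sample <- function(x, ...) {
  cat(sprintf("DTPLN sample: n = %d (%d zeros, %d positive)\n",
              x$n, x$n0, x$n1))
  if (x$n1 > 0)
    cat(sprintf("  positives: min = %g, mean = %.4f, max = %g\n",
                x$min_pos, mean(x$positives), max(x$positives)))
  invisible(x)
}

as_sample <- function(x) {
  if (inherits(x, "dtpln_sample")) x else sample_data(x)
}
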