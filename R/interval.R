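# Shared interval container used by all six methods.

new_interval <- function(lower, upper, level, method, scale = "log-mean") {
  stopifnot(is.finite(lower), is.finite(upper), lower <= upper)
  structure(list(lower = lower, upper = upper, level = level,
                 method = method, scale = scale),
            class = "dtpln_interval")
}

#' Width of an interval
#'
#' @param x a `"dtpln_interval"` object.
#' @return `upper - lower` on the interval's own scale.
#' @export
interval_width <- function(x) {
  stopifnot(inherits(x, "dtpln_interval"))
  x$upper - x$lower
}

#' Exponentiate a log-mean interval to the original scale
#'
#' @param x a `"dtpln_interval"` object on the log-mean scale.
#' @return The same interval with both bounds exponentiated.
#' @export
interval_exp <- function(x) {
  stopifnot(inherits(x, "dtpln_interval"), identical(x$scale, "log-mean"))
  new_interval(exp(x$lower), exp(x$upper), x$level, x$method,
               scale = "original")
}

#' @export
print.dtpln_interval <- function(x, ...) {
  cat(sprintf("%d%% %s interval (%s scale): [%.4f, %.4f]  width %.4f\n",
              round(100 * x$level), x$method, x$scale,
              x$lower, x$upper, interval_width(x)))
  invisible(x)
}

#' @export
as.double.dtpln_interval <- function(x, ...) c(x$lower, x$upper)

#' Equal-tailed interval from simulated draws
#'
#' The `alpha/2` and `1 - alpha/2` empirical quantiles of a draw vector, with
#' the usual linear order-statistic interpolation (`h = (m - 1) q + 1`,
#' `quantile()` type 7).
#'
#' @param draws numeric vector of simulated values, or an object with a
#'   `theta` component such as a posterior or GPQ draw set. In routine use a
#'   few thousand draws are needed for stable tail quantiles.
#' @param level confidence level (default 0.95).
#' @param method label attached to the returned interval.
#' @return A `"dtpln_interval"`.
#' @export
equal_tailed <- function(draws, level = 0.95, method = "equal-tailed") {
  draws <- extract_theta(draws)
  stopifnot(length(draws) >= 2, level > 0, level < 1)
  alpha <- 1 - level
  q <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2),
                       names = FALSE, type = 7)
  new_interval(q[1], q[2], level, method)
}

#' Highest-posterior-density interval from simulated draws
#'
#' Among all windows of `k = ceiling(level * m)` consecutive sorted draws,
#' returns the narrowest (ties broken by the smallest lower bound). For a
#' unimodal posterior this converges to the shortest region of the requested
#' posterior content, in which the density is nowhere below the density
#' outside.
#'
#' @inheritParams equal_tailed
#' @return A `"dtpln_interval"`.
#' @export
hpd_interval <- function(draws, level = 0.95, method = "HPD") {
  draws <- extract_theta(draws)
  m <- length(draws)
  stopifnot(m >= 2, level > 0, level < 1)
  s <- sort(draws)
  k <- ceiling(level * m)
  if (k >= m) return(new_interval(s[1], s[m], level, method))
  widths <- s[k:m] - s[seq_len(m - k + 1)]
  i <- which.min(widths) # first minimum = smallest lower bound among ties
  new_interval(s[i], s[i + k - 1], level, method)
}

extract_theta <- function(x) {
  if (is.numeric(x)) return(x)
  if (!is.null(x$theta)) return(x$theta)
  stop("expected a numeric vector or an object with a 'theta' component")
}
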