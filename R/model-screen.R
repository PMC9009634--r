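# AIC/BIC screening of candidate families for the positive part of the data.

#' Information criteria from a maximized log-likelihood
#'
#' Standard forms: `AIC = -2 loglik + 2k` and `BIC = -2 loglik + k log(n)`,
#' so `BIC - AIC = k (log(n) - 2)` exactly.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters (`>= 1`).
#' @param n number of observations (`>= 2`).
#' @return `c(aic = ..., bic = ...)`.
#' @export
aic_bic <- function(loglik, k, n) {
  stopifnot(k >= 1, n >= 2, is.finite(loglik))
  c(aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n))
}

# Maximum likelihood fit of one candidate family via MASS::fitdistr;
# returns NULL on failure.
.fit_family <- function(y, name) {
  k <- switch(name, exponential = 1L, `t` = 3L, 2L)
  densname <- switch(name, lognormal = "log-normal", name)
  # optim explores invalid scales along the way; those NaN warnings are benign
  fit <- tryCatch(suppressWarnings(MASS::fitdistr(y, densname)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  ll <- as.numeric(stats::logLik(fit))
  ic <- aic_bic(ll, k, length(y))
  data.frame(name = name, k = k, loglik = ll,
             aic = ic[["aic"]], bic = ic[["bic"]], n = length(y))
}

#' Screen candidate distributions for the positive observations
#'
#' Fits a panel of location-scale and positive-support families by maximum
#' likelihood to the (optionally threshold-reduced) positive data and ranks
#' them by AIC. Families whose support excludes some observations (for
#' example the exponential on data containing nonpositive values) are skipped
#' with a note, as are families whose optimization fails.
#'
#' @param positives vector of at least 5 positive observations.
#' @param reduce_by amount subtracted from every observation before fitting
#'   (typically the threshold estimate); default 0.
#' @param families candidate family names; default the full panel of Cauchy,
#'   exponential, gamma, logistic, lognormal, normal, Student-t
#'   (location-scale) and Weibull.
#' @return A data.frame sorted by AIC with columns `name`, `k`, `loglik`,
#'   `aic`, `bic`, `n`, and attribute `"best"` (lowest-AIC family). Skipped
#'   families are recorded in attribute `"skipped"`.
#' @export
#' @examples
#' fit <- dtpln_fit(rainfall_fixture())
#' fit_candidates(fit$sample$positives, reduce_by = fit$a_hat)
fit_candidates <- function(positives, reduce_by = 0,
                           families = c("cauchy", "exponential", "gamma",
                                        "logistic", "lognormal", "normal",
                                        "t", "weibull")) {
  stopifnot(length(positives) >= 5, all(positives > 0))
  y <- positives - reduce_by
  skipped <- character(0)
  rows <- list()
  positive_only <- c("exponential", "gamma", "lognormal", "weibull")
  for (f in families) {
    if (f %in% positive_only && any(y <= 0)) {
      skipped <- c(skipped, f)
      next
    }
    r <- .fit_family(y, f)
    if (is.null(r)) skipped <- c(skipped, f) else rows[[f]] <- r
  }
  if (!length(rows)) stop("every candidate family failed to fit")
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  attr(out, "best") <- out$name[1]
  attr(out, "skipped") <- skipped
  out
}
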