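rain <- rainfall_fixture()

test_that("zero-proportion estimate is the zero fraction", {
  expect_equal(estimate_delta(7, 62), 0.1129, tolerance = 5e-5)
  expect_identical(estimate_delta(0, 50), 0)
  expect_identical(estimate_delta(5, 10), 0.5)
})

test_that("modified-moment threshold reproduces the rainfall estimate", {
  a_hat <- estimate_threshold(rain$positives)
  expect_equal(as.numeric(a_hat), 1.7604, tolerance = 5e-4)
  expect_true(attr(a_hat, "converged"))
})

test_that("threshold estimate is shift equivariant and respects its bounds", {
  x <- tpln_sample(80, 2, 0.5, 3, seed = 4)
  a1 <- as.numeric(estimate_threshold(x))
  a2 <- as.numeric(estimate_threshold(x + 2.5))
  expect_equal(a2, a1 + 2.5, tolerance = 1e-6)
  expect_lt(a1, min(x))
  expect_gte(a1, 0)
  a_raw <- estimate_threshold(x, variant = "raw")
  expect_true(as.numeric(a_raw) >= 0 && as.numeric(a_raw) < min(x))
})

test_that("threshold estimator recovers the true threshold in simulation", {
  a_hats <- vapply(seq_len(150), function(i) {
    x <- tpln_sample(200, 2, 0.5, 10, seed = 1000 + i)
    suppressWarnings(as.numeric(estimate_threshold(x)))
  }, numeric(1))
  expect_lt(abs(median(a_hats) - 10), 0.5)
})

test_that("threshold score equals the likelihood derivative", {
  x <- tpln_sample(40, 1.5, 0.4, 2, seed = 9)
  s <- sample_data(x)
  mu <- 1.4; s2 <- 0.5; h <- 1e-6
  for (a in seq(0.1, 0.9 * min(x), length.out = 10)) {
    num <- (dtpln_loglik(dtpln_params(0.2, mu, s2, a + h), s) -
            dtpln_loglik(dtpln_params(0.2, mu, s2, a - h), s)) / (2 * h)
    expect_equal(threshold_score(a, x, mu, s2), num, tolerance = 1e-4)
  }
  # residual is finite over the admissible range
  grid <- seq(0, 0.99 * min(x), length.out = 200)
  vals <- vapply(grid, threshold_score, numeric(1), positives = x)
  expect_true(all(is.finite(vals)))
  # with location/scale held fixed, the score changes sign before min(x):
  # the (log(x1 - a) - mu) / (x1 - a) term dominates negatively at the edge
  edge <- vapply(c(0.5, 0.999999) * min(x), threshold_score, numeric(1),
                 positives = x, mu = mu, sigma2 = s2)
  expect_gt(edge[1] * edge[2], -Inf)
  expect_true(sign(edge[1]) != sign(edge[2]))
  expect_error(threshold_score(min(x), x), "smallest")
})

test_that("location/scale estimates match closed forms", {
  est <- estimate_location_scale(rain$positives, 1.7604)
  expect_equal(est$mu, 3.705659, tolerance = 1e-6)
  expect_equal(est$s2, 1.048613, tolerance = 1e-6)
  a <- 3
  two <- c(a + 1, a + exp(2))
  e1 <- estimate_location_scale(two, a, "unbiased")
  e2 <- estimate_location_scale(two, a, "mle")
  expect_equal(e1$mu, 1)
  expect_equal(e1$s2, 2)
  expect_equal(e2$s2, 1)
  eq <- estimate_location_scale(rep(a + exp(1), 4), a)
  expect_equal(eq$mu, 1)
  expect_equal(eq$s2, 0)
  expect_error(estimate_location_scale(c(2, 4), 2), "exceed")
})

test_that("threshold variance follows the closed form and 1/n1 scaling", {
  expect_equal(threshold_variance(0, 1, 10), 0.01509829, tolerance = 1e-6)
  expect_equal(threshold_variance(0, 1, 20),
               threshold_variance(0, 1, 10) / 2)
  expect_equal(threshold_variance(3.7256, 1.0489, 55), 4.182108,
               tolerance = 1e-5)
  expect_gt(threshold_variance(-3, 2, 5), 0)
})

test_that("log-likelihood is a sum of per-observation log densities", {
  x <- c(0, 0, tpln_sample(10, 1, 0.5, 2, seed = 3))
  s <- sample_data(x)
  p1 <- dtpln_params(0.2, 1.1, 0.6, 1.5)
  p2 <- dtpln_params(0.3, 0.9, 0.4, 1.0)
  per_point <- function(p) {
    s$n0 * log(p$delta) +
      sum(log((1 - p$delta) * tpln_pdf(s$positives, p)))
  }
  expect_equal(dtpln_loglik(p1, s) - dtpln_loglik(p2, s),
               per_point(p1) - per_point(p2), tolerance = 1e-10)
  expect_identical(dtpln_loglik(dtpln_params(0.2, 1, 1, min(s$positives)), s),
                   -Inf)
})

test_that("likelihood is maximized at the MLE identities", {
  x <- c(0, 0, 0, tpln_sample(30, 2, 0.4, 5, seed = 12))
  s <- sample_data(x)
  a <- 4.5
  mle <- estimate_location_scale(s$positives, a, "mle")
  d_hat <- s$n0 / s$n
  best <- dtpln_loglik(dtpln_params(d_hat, mle$mu, mle$s2, a), s)
  for (dm in c(-0.05, 0.07)) for (ds in c(-0.05, 0.08)) {
    expect_lt(dtpln_loglik(
      dtpln_params(d_hat, mle$mu + dm, mle$s2 + ds, a), s), best)
  }
  # zero gradient in delta at n0/n
  expect_lt(dtpln_loglik(dtpln_params(d_hat + 0.02, mle$mu, mle$s2, a), s),
            best)
  expect_lt(dtpln_loglik(dtpln_params(d_hat - 0.02, mle$mu, mle$s2, a), s),
            best)
})

test_that("full fit composes the estimators coherently", {
  fit <- dtpln_fit(rain)
  expect_equal(fit$delta_hat, 7 / 62)
  expect_equal(fit$a_hat, 1.7604, tolerance = 5e-4)
  expect_equal(fit$mu_hat, 3.705659, tolerance = 1e-5)
  expect_equal(fit$s2_unbiased, 1.048613, tolerance = 1e-5)
  expect_equal(fit$s2_mle / fit$s2_unbiased, 54 / 55)
  expect_lt(fit$a_hat, fit$min_pos)
  expect_equal(fit$mean_pos, mean(rain$positives))
  expect_equal(fit$mean_hat, exp(fit$theta_hat))
  # true threshold near zero: the zero-fallback warning is expected here
  nf <- suppressWarnings(dtpln_fit(tpln_sample(50, 2, 0.5, 1, seed = 8)))
  expect_identical(nf$delta_hat, 0)
  expect_identical(nf$n0, 0L)
})

test_that("fit recovers the generating parameters in simulation", {
  for (a in c(1, 5, 15)) {
    reps <- 40
    out <- t(vapply(seq_len(reps), function(i) {
      s <- rdtpln(2000, dtpln_params(0.3, 2, 0.5, a), seed = a * 1e4 + i)
      f <- suppressWarnings(dtpln_fit(s))
      c(f$delta_hat, f$mu_hat, f$s2_unbiased, f$a_hat)
    }, numeric(4)))
    expect_lt(abs(mean(out[, 1]) - 0.3),
              3 * sd(out[, 1]) / sqrt(reps) + 1e-3)
    expect_lt(abs(median(out[, 4]) - a), 1)
    expect_lt(abs(mean(out[, 2]) - 2), 3 * sd(out[, 2]) / sqrt(reps) + 0.05)
    expect_lt(abs(mean(out[, 3]) - 0.5), 3 * sd(out[, 3]) / sqrt(reps) + 0.05)
  }
})
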