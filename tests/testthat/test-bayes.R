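rain_fit <- dtpln_fit(rainfall_fixture())

test_that("threshold kernel matches direct products and is monotone", {
  p <- c(10, 20, 40)
  expect_equal(threshold_log_kernel(5, p) - threshold_log_kernel(0, p),
               1.114361, tolerance = 1e-6)
  expect_equal(threshold_log_kernel(0, p), -sum(log(p)))
  grid <- seq(0, 9.99, length.out = 500)
  expect_true(all(diff(threshold_log_kernel(grid, p)) >= 0))
  expect_identical(threshold_log_kernel(10, p), -Inf)
  expect_identical(threshold_log_kernel(-0.1, p), -Inf)
})

test_that("Metropolis sampler stays in support and is seed-reproducible", {
  p <- c(8, 12, 30, 50)
  d1 <- sample_threshold_posterior(p, 500, seed = 3)
  d2 <- sample_threshold_posterior(p, 500, seed = 3)
  expect_identical(as.numeric(d1), as.numeric(d2))
  expect_true(all(d1 >= 0 & d1 < 8))
  expect_true(attr(d1, "acceptance") > 0.05 && attr(d1, "acceptance") < 0.95)
})

test_that("Metropolis long-run distribution matches the quadrature-normalized kernel", {
  p <- c(10, 100, 100, 100)
  cdf <- kernel_cdf_quadrature(p)
  d <- sort(sample_threshold_posterior(p, 5e4, seed = 5, burnin = 1000))
  Fd <- cdf(d)
  m <- length(d)
  ks <- max(abs(Fd - seq_len(m) / m), abs(Fd - (seq_len(m) - 1) / m))
  expect_lt(ks, 0.05)
})

test_that("posterior component moments match their closed forms (NI1)", {
  m <- 1e5
  post <- draw_posterior(rain_fit, "NI1", m = m, seed = 21)
  n0 <- rain_fit$n0; n1 <- rain_fit$n1; s2 <- rain_fit$s2_unbiased
  mse <- function(x) 3 * sd(x) / sqrt(m)
  expect_lt(abs(mean(post$delta) - (n0 + 0.5) / (n0 + n1 + 2)),
            mse(post$delta))
  expect_lt(abs(mean(post$sigma2) - ((n1 - 1) * s2 / 2) / (n1 / 2 - 1)),
            mse(post$sigma2))
  expect_lt(abs(mean(post$mu) - rain_fit$mu_hat), mse(post$mu))
  df <- n1 - 1
  expect_lt(abs(var(post$mu) - df / (df - 2) * s2 / n1),
            3 * var(post$mu) * sqrt(2 / m) * 3)
})

test_that("posterior component moments match their closed forms (NI2)", {
  m <- 1e5
  post <- draw_posterior(rain_fit, "NI2", m = m, seed = 22)
  n0 <- rain_fit$n0; n1 <- rain_fit$n1; s2 <- rain_fit$s2_unbiased
  cc <- 1 / 3 + qnorm(0.975)^2 / 6
  expect_equal(cc, 0.9735765, tolerance = 1e-6)
  mse <- function(x) 3 * sd(x) / sqrt(m)
  expect_lt(abs(mean(post$delta) - (n0 + cc) / (n0 + n1 + 2 * cc)),
            mse(post$delta))
  expect_lt(abs(mean(post$sigma2) - ((n1 - 1) * s2 / 2) / ((n1 - 1) / 2 - 1)),
            mse(post$sigma2))
  expect_lt(abs(mean(post$mu) - rain_fit$mu_hat), mse(post$mu))
})

test_that("printed NI2 location scale is exactly half the standard one", {
  m <- 2000
  p_std <- draw_posterior(rain_fit, "NI2", m = m, seed = 33,
                          ni2_mu_scale = "standard")
  p_prt <- draw_posterior(rain_fit, "NI2", m = m, seed = 33,
                          ni2_mu_scale = "as_printed")
  r <- (p_prt$mu - rain_fit$mu_hat) / (p_std$mu - rain_fit$mu_hat)
  expect_equal(range(r), rep(1 / sqrt(2), 2), tolerance = 1e-8)
})

test_that("theta draws satisfy the assembly identity elementwise", {
  post <- draw_posterior(rain_fit, "NI1", m = 2000, seed = 13,
                         threshold_method = "mcmc")
  expect_equal(post$theta,
               log1p(-post$delta) + log(post$a + exp(post$mu + post$sigma2 / 2)),
               tolerance = 1e-12)
  expect_true(all(post$delta > 0 & post$delta < 1))
  expect_true(all(post$a >= 0 & post$a < rain_fit$min_pos))
  expect_true(all(post$sigma2 > 0))
})

test_that("plug-in threshold mode pins the threshold at its estimate", {
  post <- draw_posterior(rain_fit, "NI1", m = 500, seed = 14)
  expect_identical(unique(post$a), rain_fit$a_hat)
})

test_that("parameter blocks are drawn independently", {
  post <- draw_posterior(rain_fit, "NI1", m = 1e5, seed = 15)
  expect_lt(abs(cor(post$delta, post$sigma2)), 0.02)
  expect_lt(abs(cor(post$delta, post$mu)), 0.02)
})

test_that("HPD-NI1 intervals are frequentist-calibrated at a large threshold", {
  r <- run_scenario(delta = 0.3, mu = 2, sigma2 = 0.5, a = 15, n = 50,
                    reps = 1200, m = 1200, methods = "HPD-NI1", seed = 7)
  expect_gte(r$cp, 0.94)
  expect_lte(r$cp, 0.97)
})
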