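test_that("log-mean theta matches closed-form evaluations", {
  expect_equal(dtpln_theta(dtpln_params(0, 2, 2, 0)), 3)
  expect_equal(dtpln_theta(dtpln_params(0.5, 0, 2, 1)), 0.6201145,
               tolerance = 1e-6)
  # rainfall-scale parameter values
  p <- dtpln_params(0.1129, 3.7256, 1.0489, 1.7604)
  expect_equal(dtpln_theta(p), 4.155052, tolerance = 1e-5)
  expect_equal(dtpln_mean(p), 63.75527, tolerance = 1e-4)
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(dtpln_params(1, 2, 1, 0), "delta")
  expect_error(dtpln_params(-0.1, 2, 1, 0), "delta")
  expect_error(dtpln_params(0.2, 2, 0, 0), "sigma2")
  expect_error(dtpln_params(0.2, 2, 1, -1), "'a'")
  expect_silent(dtpln_params(0, 2, 1, 0)) # pure three-parameter lognormal
})

test_that("CDF has the zero point mass, flat gap, and shifted-lognormal tail", {
  p <- dtpln_params(0.3, 1.5, 0.8, 4)
  expect_equal(dtpln_cdf(0, p), 0.3)
  expect_equal(dtpln_cdf(2, p), 0.3)
  expect_equal(dtpln_cdf(4, p), 0.3) # no mass on (0, a]
  expect_equal(dtpln_cdf(4 + exp(1.5), p), 0.3 + 0.7 * 0.5) # shifted median
  grid <- seq(0, 500, length.out = 4000)
  expect_true(all(diff(dtpln_cdf(grid, p)) >= 0))
  expect_lt(abs(dtpln_cdf(1e6, p) - 1), 1e-9)
})

test_that("with a = 0 the CDF reduces to the delta-lognormal special case", {
  p <- dtpln_params(0.25, 1, 0.6, 0)
  x <- c(0, 0.5, 1, 3, 10, 50)
  ref <- ifelse(x > 0, 0.25 + 0.75 * plnorm(x, 1, sqrt(0.6)), 0.25)
  expect_equal(dtpln_cdf(x, p), ref, tolerance = 1e-12)
})

test_that("positive-part density integrates to one and matches a change of variables", {
  p <- dtpln_params(0.2, 2, 0.5, 5)
  expect_equal(tpln_pdf(5 + exp(2), dtpln_params(0.2, 2, 1, 5)),
               exp(-2) / sqrt(2 * pi), tolerance = 1e-12)
  # piecewise: the integrand is sharply peaked near a + exp(mu)
  cuts <- c(5, 100, 5000, 5 + 1e6)
  total <- sum(vapply(seq_len(3), function(i)
    integrate(function(x) tpln_pdf(x, p), cuts[i], cuts[i + 1],
              rel.tol = 1e-9)$value, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-6)
  x <- 5 + exp(seq(-2, 4, length.out = 100))
  ref <- dnorm(log(x - 5), 2, sqrt(0.5)) / (x - 5)
  expect_equal(tpln_pdf(x, p), ref, tolerance = 1e-12)
  expect_error(tpln_pdf(c(6, 5), p), "threshold")
})

test_that("sampler honors the mixture structure and is reproducible", {
  p0 <- dtpln_params(0, 2, 0.5, 5)
  expect_identical(rdtpln(1000, p0, seed = 1)$n0, 0L)
  p <- dtpln_params(0.3, 2, 0.5, 5)
  s <- rdtpln(1e5, p, seed = 2)
  expect_lt(abs(s$n0 / s$n - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
  se <- sd(s$values) / sqrt(s$n)
  expect_lt(abs(mean(s$values) - 10.14142), 3 * se)
  expect_true(all(s$positives > 5))
  s2 <- rdtpln(1e5, p, seed = 2)
  expect_identical(s$values, s2$values)
})

test_that("Monte Carlo mean matches exp(theta) across a parameter grid", {
  grid <- expand.grid(delta = c(0.1, 0.3, 0.5), a = c(0, 1, 15),
                      sigma2 = c(0.3, 1.0))
  for (i in seq_len(nrow(grid))) {
    p <- dtpln_params(grid$delta[i], 2, grid$sigma2[i], grid$a[i])
    s <- rdtpln(1e5, p, seed = 100 + i)
    se <- sd(s$values) / sqrt(s$n)
    expect_lt(abs(mean(s$values) - exp(dtpln_theta(p))), 4 * se)
  }
})

test_that("sample container records the zero/positive partition", {
  s <- sample_data(c(0, 1.5, 0, 2.5, 3))
  expect_identical(s$n, 5L)
  expect_identical(s$n0, 2L)
  expect_identical(s$n1, 3L)
  expect_identical(s$n, s$n0 + s$n1)
  expect_equal(s$min_pos, 1.5)
  expect_error(sample_data(c(-1, 2)), "nonnegative")
  expect_true(is.na(sample_data(c(0, 0))$min_pos))
})
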