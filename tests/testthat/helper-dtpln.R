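# Shared test helpers: independent oracles and small generators.

# O(m^2)-style brute force: scan every window of k consecutive sorted draws.
hpd_brute <- function(draws, level) {
  s <- sort(draws)
  m <- length(s)
  k <- ceiling(level * m)
  best <- c(s[1], s[m])
  for (i in seq_len(m - k + 1)) {
    if (s[i + k - 1] - s[i] < best[2] - best[1])
      best <- c(s[i], s[i + k - 1])
  }
  best
}

# shifted-lognormal sample without going through the package generator
tpln_sample <- function(n, mu, s2, a, seed) {
  set.seed(seed)
  a + exp(rnorm(n, mu, sqrt(s2)))
}

# quadrature CDF of the truncated threshold posterior prod(x_i - a)^(-1)
# on [0, hi]; computed on a log-boundary-layer grid so the near-singular
# endpoint is resolved. Returns a function a -> F(a).
kernel_cdf_quadrature <- function(positives, trunc_eps = 1e-6) {
  x1 <- min(positives)
  hi <- x1 * (1 - trunc_eps)
  u <- seq(-log(hi), -log(x1 * trunc_eps) + 8, length.out = 200001)
  a <- hi - exp(-u)
  lk <- -vapply(a, function(ai) sum(log(positives - ai)), numeric(1))
  g <- exp(lk - max(lk)) * exp(-u) # density in u coordinates
  w <- diff(u) * (g[-1] + g[-length(g)]) / 2
  cdf <- c(0, cumsum(w))
  cdf <- cdf / cdf[length(cdf)]
  function(q) approx(a, cdf, xout = q, rule = 2, ties = "ordered")$y
}

# fit-shaped object with hand-set estimates, for pivotal/interval unit tests
fake_fit <- function(delta_hat = 0.1, a_hat = 1, mu_hat = 2,
                     s2 = 0.5, var_a_hat = 1, n0 = 5, n1 = 45) {
  structure(list(
    delta_hat = delta_hat, a_hat = a_hat, mu_hat = mu_hat,
    s2_unbiased = s2, s2_mle = s2 * (n1 - 1) / n1,
    var_a_hat = var_a_hat, n = n0 + n1, n0 = n0, n1 = n1,
    min_pos = a_hat + 1e-3, mean_pos = NA_real_,
    theta_hat = log1p(-delta_hat) + log(a_hat + exp(mu_hat + s2 / 2)),
    mean_hat = NA_real_, threshold_converged = TRUE, sample = NULL
  ), class = "dtpln_fit")
}
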