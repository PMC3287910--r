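test_that("noise sd estimate follows the MAD convention", {
  expect_equal(estimate_noise_sd(c(-0.6745, 0.6745, 0.6745, -0.6745)), 1.0)
  expect_equal(estimate_noise_sd(numeric(4)), 0)
  set.seed(2)
  d <- rnorm(40)
  expect_equal(estimate_noise_sd(10 * d), 10 * estimate_noise_sd(d))
})

test_that("marginal ML weight is small for pure noise, large for spikes", {
  set.seed(14)
  z_noise <- rnorm(500)
  expect_lte(marginal_mle_weight(z_noise, a = 0.5, sigma = 1), 0.1)
  z_spike <- c(rnorm(250), sample(c(-10, 10), 250, replace = TRUE))
  expect_gte(marginal_mle_weight(z_spike, a = 0.5, sigma = 1), 0.4)
})

test_that("marginal ML weight maximises the marginal likelihood", {
  # compare against a grid search over an independently computed likelihood
  # (numeric convolution of the Laplace slab with the Gaussian noise)
  set.seed(8)
  cases <- list(rnorm(60), c(rnorm(40), rnorm(20, 0, 4)), rnorm(30, 2))
  for (z in cases) {
    w_hat <- marginal_mle_weight(z, a = 0.5, sigma = 1)
    expect_gte(w_hat, 0)
    expect_lte(w_hat, 1)
    grid <- seq(0, 1, by = 0.002)
    ll <- vapply(grid, oracle_loglik_w, numeric(1), z = z, a = 0.5)
    expect_gte(oracle_loglik_w(w_hat, z, 0.5), max(ll) - 1e-4)
  }
})

test_that("posterior median matches the quadrature oracle", {
  grid <- expand.grid(z = c(-4, 0.5, 1, 2, 5, 8),
                      w = c(0.05, 0.3, 0.7, 1),
                      a = c(0.3, 0.5, 1),
                      sigma = c(1, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    post <- ebayes_posterior(g$w, g$a, g$sigma)
    expect_equal(posterior_median(g$z, post),
                 oracle_postmed(g$z, g$w, g$a, g$sigma),
                 tolerance = 1e-6,
                 info = sprintf("z=%g w=%g a=%g sigma=%g",
                                g$z, g$w, g$a, g$sigma))
  }
  # frozen oracle value for the reference case
  expect_equal(posterior_median(5, ebayes_posterior(0.5, 0.5, 1)),
               4.4999205955, tolerance = 1e-6)
})

test_that("posterior median is antisymmetric, shrinking, and sparse", {
  post <- ebayes_posterior(0.4, 0.5, 1.3)
  z <- seq(-8, 8, by = 0.37)
  med <- posterior_median(z, post)
  expect_equal(med, -posterior_median(-z, post))
  expect_true(all(abs(med) <= abs(z) + 1e-12))
  expect_true(all((med == 0) == (abs(z) <= post$t_of_w)))
  # degenerate mixing weights
  expect_equal(posterior_median(c(-3, 0, 5), ebayes_posterior(0, 0.5, 1)),
               c(0, 0, 0))
  expect_equal(posterior_median(0, post), 0)
})

test_that("threshold is the exact zero/nonzero boundary and decreases in w", {
  for (w in c(0.05, 0.3, 0.8)) {
    post <- ebayes_posterior(w, 0.5, 1)
    tt <- post$t_of_w
    expect_identical(posterior_median(tt - 1e-6, post), 0)
    expect_gt(abs(posterior_median(tt + 1e-5, post)), 0)
  }
  tw <- vapply(c(0.05, 0.2, 0.5, 0.9, 1), threshold_value, numeric(1),
               a = 0.5, sigma = 1)
  expect_true(all(diff(tw) <= 1e-8))
  expect_identical(threshold_value(0, 0.5, 1), Inf)
  expect_lt(threshold_value(1, 0.5, 1), 1e-6)
  # scales linearly with the noise level
  expect_equal(threshold_value(0.3, 0.5, 2), 2 * threshold_value(0.3, 0.5, 1),
               tolerance = 1e-6)
})
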