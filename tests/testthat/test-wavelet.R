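test_that("Haar transform matches the hand-computed filter values", {
  pyr <- dwt(c(1, 1, -1, -1), wavelet_config(max_level = 1))
  expect_equal(pyr$approximation, c(sqrt(2), -sqrt(2)))
  expect_equal(pyr$details[[1]], c(0, 0))
})

test_that("constant signals have zero detail coefficients", {
  pyr <- dwt(rep(3.7, 16))
  for (d in pyr$details) expect_equal(d, rep(0, length(d)))
})

test_that("dwt/idwt round-trips to machine precision for both families", {
  set.seed(101)
  for (family in c("haar", "d4")) {
    for (len in c(2, 8, 13, 32, 100)) {
      x <- rnorm(len)
      pyr <- dwt(x, wavelet_config(family = family))
      expect_lt(max(abs(idwt(pyr) - x)), 1e-10)
      expect_equal(pyr$original_length, len)
    }
  }
})

test_that("dwt rejects degenerate input", {
  expect_error(dwt(1), "length")
  expect_error(dwt(c(1, NA, 2)), "finite")
})

test_that("denoising is a no-op on zeros and constants", {
  expect_equal(denoise_signal(numeric(16)), numeric(16))
  expect_equal(denoise_signal(rep(2, 16)), rep(2, 16), tolerance = 1e-12)
})

test_that("denoise with shrinkage disabled is the identity", {
  set.seed(5)
  x <- rnorm(23)
  out <- denoise_signal(x, wavelet_config(shrink = "none"))
  expect_lt(max(abs(out - x)), 1e-10)
})

test_that("denoising reduces mean squared error on a noisy block signal", {
  set.seed(3)
  clean <- rep(c(0, 2, 0, 1), each = 16)
  noisy <- clean + rnorm(64, 0, 0.1)
  den <- denoise_signal(noisy)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
})

test_that("every detail coefficient shrinks in magnitude", {
  set.seed(9)
  x <- rep(c(0, 1), each = 16) + rnorm(32, 0, 0.2)
  den <- denoise_signal(x)
  pin <- dwt(x)
  pout <- dwt(den)
  for (lev in seq_along(pin$details)) {
    expect_true(all(abs(pout$details[[lev]]) <=
                      abs(pin$details[[lev]]) + 1e-10))
  }
})

test_that("an isolated large value survives individual-level thresholding", {
  # a rare variant carried against a near-flat background must not be
  # smoothed away; at least half its amplitude is retained
  set.seed(11)
  x <- rnorm(32, 0, 0.1)
  x[10] <- x[10] + 5
  den <- denoise_signal(x)
  expect_gt(den[10], 0.5 * x[10])
})

test_that("zero MAD falls back to the detail standard deviation", {
  # an exactly-zero background makes the finest-level MAD zero; the noise
  # scale must fall back to the sd of all details instead of dividing by 0
  sp <- numeric(32)
  sp[10] <- 5
  d <- denoise_signal(sp)
  expect_true(all(is.finite(d)))
  expect_gt(max(abs(d)), 1) # the isolated signal is shrunk, not erased
  expect_identical(which.max(abs(d)), 10L)
})

test_that("matrix denoising treats rows independently", {
  set.seed(21)
  X <- matrix(rnorm(5 * 16), 5, 16)
  whole <- denoise_matrix(X)
  rowwise <- t(vapply(seq_len(5), function(i) denoise_signal(X[i, ]),
                      numeric(16)))
  expect_equal(whole, rowwise, tolerance = 1e-12)
})
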