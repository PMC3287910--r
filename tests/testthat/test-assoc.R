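test_that("column centring zeroes every SNP mean", {
  expect_equal(center_window(matrix(1, 4, 1)), matrix(0, 4, 1))
  expect_equal(center_window(matrix(c(0, 2), 2, 1)), matrix(c(-1, 1), 2, 1))
  set.seed(12)
  xc <- center_window(matrix(rnorm(40), 8, 5))
  expect_lt(max(abs(colMeans(xc))), 1e-12)
  xr <- center_window(matrix(rnorm(40), 8, 5), center = "positions")
  expect_lt(max(abs(rowMeans(xr))), 1e-12)
})

test_that("score statistic matches the hand-computed example", {
  s <- score_statistic(matrix(c(-1, -1, 1, 1), ncol = 1), c(-1, -1, 1, 1))
  expect_equal(s$U, 4)
  expect_equal(s$V_j, 16 / 3)
  expect_equal(s$T, sqrt(3))
  # degenerate and antisymmetric cases
  expect_identical(score_statistic(matrix(c(-1, -1, 1, 1), ncol = 1),
                                   rep(0, 4))$T, 0)
  set.seed(30)
  xc <- center_window(matrix(rnorm(60), 12, 5))
  y <- rnorm(12)
  expect_equal(score_statistic(xc, -y)$T, -score_statistic(xc, y)$T)
})

test_that("score statistic equals the loop-based oracle on random data", {
  set.seed(88)
  for (r in 1:100) {
    n <- sample(4:30, 1)
    m <- sample(1:8, 1)
    xc <- center_window(matrix(rnorm(n * m), n, m))
    y <- rnorm(n)
    a <- score_statistic(xc, y)
    b <- oracle_score(xc, y)
    expect_equal(a$U, b$U, tolerance = 1e-10)
    expect_equal(a$V_j, b$V_j, tolerance = 1e-10)
    expect_equal(a$T, b$T, tolerance = 1e-10)
  }
})

test_that("burden comparator collapses the window to one weighted sum", {
  set.seed(9)
  xw <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  # m = 1 reduces to the multilocus statistic
  expect_equal(burden_statistic(xw[, 1, drop = FALSE], y)$T,
               score_statistic(center_window(xw[, 1, drop = FALSE]), y)$T)
  # duplicated columns equal the doubled single column
  x1 <- matrix(c(0, 1, 2, 1), ncol = 1)
  y4 <- c(-1, 0, 2, -1)
  expect_equal(burden_statistic(cbind(x1, x1), y4)$T,
               burden_statistic(2 * x1, y4)$T)
  expect_identical(burden_statistic(xw, rep(0, 10))$T, 0)
})

test_that("permutation p-values live on the add-one lattice", {
  set.seed(51)
  xw <- matrix(rbinom(80, 2, 0.2), 20, 4)
  y <- rnorm(20)
  M <- 199
  p <- permutation_pvalue(xw, y, n_permutations = M, seed = 7)
  expect_true(p %in% ((1:(M + 1)) / (M + 1)))
  expect_gt(p, 0)
  # deterministic under the same seed
  expect_identical(p, permutation_pvalue(xw, y, n_permutations = M, seed = 7))
  # degenerate trait: all permuted statistics tie at zero
  expect_equal(permutation_pvalue(xw, rep(2, 20), n_permutations = 99,
                                  seed = 1), 1)
  # overwhelming association attains the minimum attainable p
  strong_y <- rowSums(weight_genotypes(xw)) * 10 + rnorm(20, 0, 1e-4)
  expect_equal(permutation_pvalue(xw, strong_y - mean(strong_y),
                                  n_permutations = 99, seed = 3), 1 / 100)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni_correct(2e-5, 1702), 0.03404)
  expect_equal(bonferroni_correct(0.5, 1702), 1)
  expect_equal(bonferroni_correct(0.12, 1), 0.12)
})

test_that("max-statistic p-values dominate per-window empirical p-values", {
  set.seed(61)
  xc <- center_window(matrix(rnorm(40 * 12), 40, 12))
  y <- rnorm(40)
  y <- y - mean(y)
  windows <- list(1:4, 5:8, 9:12)
  res <- maxstat_global_pvalue(xc, windows, y, n_permutations = 499, seed = 2)
  expect_true(all(res$p_maxstat >= res$p_empirical))
  # a single window reduces the maxima to its own permuted values
  res1 <- maxstat_global_pvalue(xc[, 1:4], list(1:4), y,
                                n_permutations = 499, seed = 2)
  expect_equal(res1$p_maxstat, res1$p_empirical)
})

test_that("single-SNP scan matches per-column score statistics", {
  set.seed(71)
  xc <- center_window(matrix(rbinom(200, 2, 0.15), 40, 5))
  y <- rnorm(40)
  y <- y - mean(y)
  sc <- single_snp_scan(xc, y)
  for (j in 1:5) {
    s <- score_statistic(xc[, j, drop = FALSE], y)
    expect_equal(sc$T[j], s$T, tolerance = 1e-12)
  }
  expect_equal(sc$p_bonferroni, pmin(1, sc$p * 5))
})
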