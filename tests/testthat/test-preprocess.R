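test_that("minor allele frequencies are allele counts over 2n", {
  expect_equal(compute_maf(matrix(c(0, 1, 2, 1), ncol = 1)), 0.5)
  expect_equal(compute_maf(matrix(c(0, 0, 0, 1), ncol = 1)), 0.125)
  expect_error(compute_maf(matrix(0, 4, 1)), "monomorphic")
  expect_error(compute_maf(matrix(2, 4, 1)), "oriented")
})

test_that("genotype weights are 1/sqrt(n q (1-q))", {
  d <- matrix(2, 25, 1)
  expect_equal(weight_genotypes(d, q = 0.2)[1, 1], 1.0)
  d2 <- matrix(c(1, rep(0, 99)), 100, 1)
  w2 <- weight_genotypes(d2, q = 0.5)
  expect_equal(w2[1, 1], 0.2)
  expect_true(all(w2[-1, 1] == 0))
  expect_error(weight_genotypes(matrix(0:1, 4, 1), q = 1), "undefined")
})

test_that("PCA separates synthetic subpopulations", {
  sim <- simulate_cohort(cohort_spec(n_individuals = 200, n_genes = 40,
                                     snps_per_gene = 8, fst = 0.1,
                                     maf_range = c(0.05, 0.3), seed = 17))
  pca <- fit_genotype_pca(sim$genotypes, 4)
  ev <- pca$eigenvalues
  expect_gt(ev[1] / ev[2], 3)
  pc1 <- pca$C[, 1]
  pop <- sim$phenotypes$population
  split_sign <- mean(sign(pc1)[pop == 1] != sign(pc1)[pop == 2][1])
  expect_gt(max(split_sign, 1 - split_sign), 0.95)
  expect_lt(max(abs(crossprod(pca$C) - diag(4))), 1e-8)
})

test_that("PCA rejects rank-deficient requests and is row-equivariant", {
  d <- matrix(c(0, 1, 2), nrow = 4, ncol = 3, byrow = TRUE)
  # identical rows: no variance left after column centring
  expect_error(fit_genotype_pca(d, 2), "rank")
  set.seed(4)
  d2 <- matrix(rbinom(30 * 20, 2, 0.3), 30, 20)
  perm <- sample(30)
  p1 <- fit_genotype_pca(d2, 2)
  p2 <- fit_genotype_pca(d2[perm, ], 2)
  # eigenvectors defined up to sign
  for (j in 1:2) {
    expect_equal(abs(p2$C[, j]), abs(p1$C[perm, j]), tolerance = 1e-8)
  }
})

test_that("eigenvalue-gap heuristic picks the visible break", {
  expect_identical(select_num_components(c(23.138, 15.087, 3, 2.9, 2.8)), 2L)
  expect_identical(select_num_components(c(10, 1, 1, 1)), 1L)
  expect_identical(select_num_components(rep(2, 6)), 0L)
})

test_that("pc_adjust projects off the components and is idempotent", {
  C <- matrix(c(1, 1) / sqrt(2), ncol = 1)
  adj <- structure(list(C = C, eigenvalues = c(1, 0), k = 1),
                   class = "ws_pca")
  expect_equal(pc_adjust(c(1, 0), adj), c(0.5, -0.5))
  set.seed(6)
  M <- matrix(rnorm(2 * 5), 2, 5)
  out <- pc_adjust(M, adj)
  expect_lt(max(abs(crossprod(C, out))), 1e-8)
  expect_equal(pc_adjust(out, adj), out, tolerance = 1e-12)
  adj0 <- structure(list(C = matrix(0, 2, 0), eigenvalues = 1, k = 0),
                    class = "ws_pca")
  expect_identical(pc_adjust(M, adj0), M)
  expect_error(pc_adjust(rnorm(3), adj), "dimension")
})

test_that("residualization removes fitted structure", {
  # exact linear dependence leaves nothing
  x <- cbind(a = c(0, 1, 2, 3))
  y <- 2 + 3 * x[, 1]
  expect_equal(residualize_trait(y, x)$values, rep(0, 4), tolerance = 1e-12)
  # an all-zero predictor column degenerates to the intercept-only fit
  y2 <- c(1, 2, 3, 6)
  expect_warning(r0 <- residualize_trait(y2, cbind(z = rep(0, 4))),
                 "collinear")
  expect_equal(r0$values, y2 - mean(y2))
  # hand-solved normal equations: slope 1.3, intercept 0.8
  r <- residualize_trait(c(1, 2, 3, 5), x)
  expect_equal(r$values, c(0.2, -0.1, -0.4, 0.3), tolerance = 1e-12)
  expect_lt(abs(mean(r$values)), 1e-8)
  expect_lt(abs(sum(r$values * x[, 1])), 1e-6)
  # collinear predictors: warning, same (unique) projection
  xx <- cbind(a = x[, 1], b = 2 * x[, 1])
  expect_warning(r2 <- residualize_trait(c(1, 2, 3, 5), xx), "collinear")
  expect_equal(r2$values, r$values, tolerance = 1e-8)
})

test_that("fixed windows partition the eligible SNPs", {
  snps <- tibble::tibble(
    id = sprintf("s%02d", 1:24),
    chromosome = "01",
    position = (1:24) * 10L,
    gene = rep(c("A", "B", "C"), each = 8),
    is_nonsynonymous = rep(c(TRUE, TRUE, TRUE, FALSE), 6)
  )
  # 18 nonsynonymous SNPs must not be double-counted in size-8 blocks
  w <- make_windows(snps, mode = "fixed", size = 8)
  expect_equal(unname(vapply(w$snp_indices, length, 1L)), c(8, 8, 2))
  idx <- sort(unlist(w$snp_indices))
  expect_identical(idx, which(snps$is_nonsynonymous))
  # 20 eligible on one chromosome -> 8, 8, 4
  snps2 <- snps[1:20, ]
  snps2$is_nonsynonymous <- TRUE
  w2 <- make_windows(snps2, mode = "fixed", size = 8)
  expect_equal(unname(vapply(w2$snp_indices, length, 1L)), c(8, 8, 4))
  # exactly one block when sizes match
  w3 <- make_windows(snps2[1:8, ], mode = "fixed", size = 8)
  expect_identical(nrow(w3), 1L)
})

test_that("gene windows skip genes with fewer than two eligible SNPs", {
  snps <- tibble::tibble(
    id = sprintf("s%d", 1:6),
    chromosome = "01",
    position = (1:6) * 10L,
    gene = c(rep("A", 5), "B"),
    is_nonsynonymous = TRUE
  )
  w <- make_windows(snps, mode = "gene")
  expect_identical(nrow(w), 1L)
  expect_identical(w$label, "A")
  expect_identical(w$snp_indices[[1]], 1:5)
  snps$is_nonsynonymous <- FALSE
  expect_error(make_windows(snps, mode = "gene"), "nonsynonymous")
})
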