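test_that("correction-comparison simulation is reproducible and bounded", {
  spec <- permcmp_spec(scenario = "same", n_null = 5000, n_reps = 200,
                       seed = 33)
  r1 <- simulate_permcmp(spec)
  r2 <- simulate_permcmp(spec)
  expect_identical(tidy(r1), tidy(r2))
  expect_true(all(r1$power >= 0 & r1$power <= 1))
  expect_true(all(r1$fwer >= 0 & r1$fwer <= 1))
  # alpha = 0 rejects nothing
  r0 <- simulate_permcmp(permcmp_spec(n_null = 2000, n_reps = 100,
                                      alpha = 0, seed = 1))
  expect_true(all(r0$power == 0) && all(r0$fwer == 0))
})

test_that("max-statistic power degrades as null heterogeneity grows", {
  powers <- vapply(c(0, 1, 2), function(s) {
    r <- simulate_permcmp(permcmp_spec(scenario = "different",
                                       n_null = 20000, n_reps = 400,
                                       a_scale = s, seed = 55))
    r$power[r$method == "maxima"]
  }, numeric(1))
  expect_gt(powers[1], powers[2])
  expect_gte(powers[2], powers[3] - 0.01)
  # while the per-variable Bonferroni route is insensitive to heterogeneity
  r_b <- vapply(c(0, 2), function(s) {
    r <- simulate_permcmp(permcmp_spec(scenario = "different",
                                       n_null = 20000, n_reps = 400,
                                       a_scale = s, seed = 55))
    r$power[r$method == "bonferroni"]
  }, numeric(1))
  expect_lt(abs(r_b[1] - r_b[2]), 0.1)
})

test_that("synthetic cohorts honour the requested structure", {
  spec <- cohort_spec(n_individuals = 697, n_genes = 10, snps_per_gene = 8,
                      n_causal_per_gene = c(3, rep(0, 9)), seed = 21)
  sim <- simulate_cohort(spec)
  expect_identical(nrow(sim$genotypes$dosages), 697L)
  expect_identical(ncol(sim$genotypes$dosages), 80L)
  expect_true(all(sim$genotypes$snps$maf > 0 & sim$genotypes$snps$maf <= 0.5))
  expect_identical(nrow(sim$truth), 3L)
  expect_true(all(sim$truth$gene == "GENE001"))
  expect_true(all(sim$phenotypes$Affected %in% c(0, 1)))
  # bit-exact reproducibility
  sim2 <- simulate_cohort(spec)
  expect_identical(sim$genotypes$dosages, sim2$genotypes$dosages)
  expect_identical(sim$phenotypes$Q1, sim2$phenotypes$Q1)
})

test_that("null cohorts yield uniform single-SNP p-values", {
  sim <- simulate_cohort(cohort_spec(n_individuals = 500, n_genes = 50,
                                     snps_per_gene = 8, fst = 0, seed = 31))
  xc <- center_window(weight_genotypes(sim$genotypes$dosages))
  y <- residualize_trait(sim$phenotypes$Q2)
  sc <- single_snp_scan(xc, y)
  expect_lt(ks_distance(sc$p), 0.08)
})

test_that("power/type-I accounting matches its definitions", {
  results <- tibble::tibble(
    replicate = rep(1:200, each = 2),
    window_id = rep(c("W1", "W2"), 200),
    p_bonferroni = c(rbind(rep(c(0.01, 1), c(136, 64)), rep(1, 200)))
  )
  truth <- tibble::tibble(window_id = c("W1", "W2"),
                          functional = c(TRUE, FALSE))
  ev <- evaluate_power_typeI(results, truth)
  expect_equal(ev$windows$rejection_rate[ev$windows$window_id == "W1"], 0.68)
  expect_equal(ev$summary$type1_per_window, 0)
  expect_equal(ev$summary$type1_per_test, 0)
  # all-ones p-values reject nothing anywhere
  results$p_bonferroni <- 1
  ev2 <- evaluate_power_typeI(results, truth)
  expect_equal(ev2$summary$mean_power, 0)
  # both aggregate conventions are reported
  expect_true(all(c("type1_per_window", "type1_per_test") %in%
                    names(ev2$summary)))
})
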