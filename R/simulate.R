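# (a) The multiple-testing comparison simulation: max-statistic versus
#     per-variable-empirical-p + Bonferroni family-wise corrections.
# (b) A synthetic cohort generator with Balding-Nichols substructure,
#     clustered rare causal variants, and covariate-driven traits.
# (c) Power / type-I accounting across replicated pipeline runs.

#' Specification of the correction-comparison simulation
#'
#' One hundred independent test statistics stand in for window tests; a
#' large null sample per statistic mimics permutation draws. Under the
#' homogeneous scenario every null statistic is standard normal; under the
#' heterogeneous scenario statistic `i` is `a(i) + b(i) e` with `a(i)` drawn
#' once from N(0,1) and `b(i)` once from Uniform(b_range). The functional
#' statistic (variable 1) keeps the standard-normal null in both scenarios
#' and equals `effect + e` under the alternative, so heterogeneity enters
#' only through the 99 null variables — the regime in which comparing to the
#' genome-wide maximum breaks down while per-variable empirical p-values do
#' not.
#'
#' @param scenario `"same"` or `"different"` null distributions.
#' @param n_vars Number of variables (default 100).
#' @param n_null Null draws per variable, mimicking permutations
#'   (default 100000).
#' @param n_reps Alternative replicates used to estimate power and
#'   family-wise error (default 1000).
#' @param effect Mean shift of the functional variable (default 3).
#' @param alpha Significance level (default 0.05).
#' @param b_range Range of the null standard deviations in the
#'   heterogeneous scenario.
#' @param a_scale Multiplier on the heterogeneous null means (1 = as
#'   specified; used for sensitivity checks).
#' @param two_sided Reject on absolute values (default `TRUE`).
#' @param seed RNG seed.
#' @return A list of class `ws_permcmp_spec`.
#' @export
permcmp_spec <- function(scenario = c("same", "different"), n_vars = 100,
                         n_null = 100000, n_reps = 1000, effect = 3,
                         alpha = 0.05, b_range = c(0.5, 1.5), a_scale = 1,
                         two_sided = TRUE, seed = 1) {
  stopifnot(n_vars >= 2, n_null >= 1, n_reps >= 1,
            alpha >= 0, alpha < 1, length(b_range) == 2)
  structure(list(scenario = match.arg(scenario), n_vars = n_vars,
                 n_null = n_null, n_reps = n_reps, effect = effect,
                 alpha = alpha, b_range = b_range, a_scale = a_scale,
                 two_sided = isTRUE(two_sided), seed = seed),
            class = "ws_permcmp_spec")
}

#' Compare max-statistic and Bonferroni permutation corrections
#'
#' Simulates the configuration in [permcmp_spec()] and evaluates both
#' family-wise correction methods on the same draws. Method `"maxima"`
#' rejects variable `i` when the proportion of per-draw maxima of all
#' variables exceeding its value is below `alpha`; method `"bonferroni"`
#' computes each variable's empirical p-value from its own null sample and
#' rejects when `p * n_vars < alpha`. Power is the rejection proportion of
#' the functional variable over the replicates; the family-wise error rate
#' is the proportion of replicates with at least one rejection among the
#' null variables.
#'
#' @param spec A [permcmp_spec()].
#' @return Tibble of class `ws_permcmp` with one row per method: `method`,
#'   `scenario`, `power`, `fwer`, `power_count`, `fwer_count`, `n_reps`.
#' @examples
#' simulate_permcmp(permcmp_spec(n_null = 2000, n_reps = 200, seed = 42))
#' @export
simulate_permcmp <- function(spec = permcmp_spec()) {
  stopifnot(inherits(spec, "ws_permcmp_spec"))
  nv <- spec$n_vars
  nn <- spec$n_null
  nr <- spec$n_reps
  set.seed(spec$seed)
  if (spec$scenario == "same") {
    a <- rep(0, nv)
    b <- rep(1, nv)
  } else {
    # variable 1 is the functional one; its null stays standard normal
    a <- c(0, rnorm(nv - 1) * spec$a_scale)
    b <- c(1, runif(nv - 1, spec$b_range[1], spec$b_range[2]))
  }
  # null sample mimicking permutation draws, one column per variable
  Z <- matrix(rnorm(nn * nv), nn, nv)
  Z <- sweep(sweep(Z, 2, b, "*"), 2, a, "+")
  if (spec$two_sided) Z <- abs(Z)
  maxima <- Z[, 1]
  for (j in 2:nv) maxima <- pmax(maxima, Z[, j])
  maxima <- sort(maxima)
  Zsort <- apply(Z, 2, sort)
  rm(Z)
  # alternative replicates: variable 1 shifted, the rest at their nulls
  Talt <- matrix(rnorm(nr * nv), nr, nv)
  Talt <- sweep(sweep(Talt, 2, b, "*"), 2, a, "+")
  Talt[, 1] <- spec$effect + rnorm(nr)
  A <- if (spec$two_sided) abs(Talt) else Talt

  # method 1: compare to the per-draw maxima ("greater than" rank)
  cnt_le <- matrix(findInterval(A, maxima), nr, nv)
  p_max <- (nn - cnt_le) / nn
  rej_max <- p_max < spec$alpha
  # method 2: per-variable empirical p, Bonferroni-corrected
  p_bon <- matrix(0, nr, nv)
  for (j in seq_len(nv)) {
    p_bon[, j] <- (nn - findInterval(A[, j], Zsort[, j])) / nn
  }
  rej_bon <- (p_bon * nv) < spec$alpha

  summarise_method <- function(rej, method) {
    tibble(method = method,
           scenario = spec$scenario,
           power = mean(rej[, 1]),
           fwer = mean(rowSums(rej[, -1, drop = FALSE]) > 0),
           power_count = sum(rej[, 1]),
           fwer_count = sum(rowSums(rej[, -1, drop = FALSE]) > 0),
           n_reps = nr)
  }
  out <- dplyr::bind_rows(summarise_method(rej_max, "maxima"),
                          summarise_method(rej_bon, "bonferroni"))
  attr(out, "spec") <- spec
  class(out) <- c("ws_permcmp", class(out))
  out
}

#' @export
tidy.ws_permcmp <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ws_permcmp")
  out
}

#' @export
glance.ws_permcmp <- function(x, ...) {
  sp <- attr(x, "spec")
  tibble(scenario = sp$scenario, n_vars = sp$n_vars, n_null = sp$n_null,
         n_reps = sp$n_reps, effect = sp$effect, alpha = sp$alpha)
}

#' @export
autoplot.ws_permcmp <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("power", "fwer"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value,
                                   fill = .data$method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Correction comparison (%s nulls)",
                                  df$scenario[1])) +
    ggplot2::theme_minimal()
}

#' Specification of a synthetic cohort
#'
#' Emulates the structure of an unrelated-individuals resequencing cohort:
#' two subpopulations with Balding-Nichols allele-frequency differentiation,
#' genes of clustered rare variants, quantitative traits driven by causal
#' variants plus Age/Sex/Smoking-style covariates, and a binary affection
#' trait generated from the quantitative traits through a logistic model.
#'
#' @param n_individuals Cohort size (default 697).
#' @param n_genes Number of genes (default 100).
#' @param snps_per_gene SNPs per gene (default 8); recycled vector allowed.
#' @param maf_range Ancestral minor-allele frequency range of the rare
#'   variants (default 0.004-0.02).
#' @param n_causal_per_gene Causal variants per gene (recycled; default 0,
#'   a fully null genome).
#' @param effect_size Trait-SD shift per causal minor allele (default 0.5).
#' @param fst Subpopulation differentiation (0 = panmictic).
#' @param pop_props Subpopulation proportions (two values summing to 1).
#' @param pop_trait_shift Mean shift of the quantitative traits between
#'   subpopulations (confounding; default 0).
#' @param covariate_effects Named list: `age`, `smoking` act on Q1; `age`,
#'   `sex`, `smoking` on Q4 (per-unit effects).
#' @param trait_noise_sd Residual SD of the quantitative traits.
#' @param prop_nonsyn Fraction of SNPs flagged nonsynonymous (default 1).
#' @param n_chromosomes Chromosomes the genes are spread over (default 22).
#' @param seed RNG seed.
#' @return A list of class `ws_cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 697, n_genes = 100,
                        snps_per_gene = 8, maf_range = c(0.004, 0.02),
                        n_causal_per_gene = 0, effect_size = 0.5,
                        fst = 0, pop_props = c(0.5, 0.5),
                        pop_trait_shift = 0,
                        covariate_effects = list(age = 0.02, sex = 0.3,
                                                 smoking = 0.4),
                        trait_noise_sd = 1, prop_nonsyn = 1,
                        n_chromosomes = 22, seed = 1) {
  stopifnot(n_individuals >= 10, n_genes >= 1, all(snps_per_gene >= 1),
            fst >= 0, fst < 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            abs(sum(pop_props) - 1) < 1e-8)
  structure(list(n_individuals = n_individuals, n_genes = n_genes,
                 snps_per_gene = snps_per_gene, maf_range = maf_range,
                 n_causal_per_gene = n_causal_per_gene,
                 effect_size = effect_size, fst = fst,
                 pop_props = pop_props, pop_trait_shift = pop_trait_shift,
                 covariate_effects = covariate_effects,
                 trait_noise_sd = trait_noise_sd,
                 prop_nonsyn = prop_nonsyn,
                 n_chromosomes = n_chromosomes, seed = seed),
            class = "ws_cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws genotypes, covariates, and traits according to a [cohort_spec()].
#' Every emitted SNP is polymorphic (columns that come out monomorphic are
#' redrawn so that window construction is stable across replicates).
#' Quantitative trait Q1 carries the causal-variant effects; Q2 and Q4 are
#' covariate-plus-noise traits; `Affected` is Bernoulli with a logistic
#' dependence on Q1, Q2, Q4, Smoking, and Age.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `genotypes` (a [genotype_matrix()]), `phenotypes`
#'   (tibble with `individual_id`, `Q1`, `Q2`, `Q4`, `Affected`, `Age`,
#'   `Sex`, `Smoking`, `population`), and `truth` (tibble of causal SNPs:
#'   `snp_id`, `gene`, `effect`).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "ws_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals
  sizes <- rep(spec$snps_per_gene, length.out = spec$n_genes)
  n_snps <- sum(sizes)
  gene_of_snp <- rep(seq_len(spec$n_genes), times = sizes)
  n_causal <- rep(spec$n_causal_per_gene, length.out = spec$n_genes)
  stopifnot(all(n_causal <= sizes))

  pop <- rep(1:2, times = c(round(n * spec$pop_props[1]), 0))
  pop <- c(pop, rep(2L, n - length(pop)))

  q0 <- runif(n_snps, spec$maf_range[1], spec$maf_range[2])
  draw_col <- function(j) {
    if (spec$fst > 0) {
      sh <- (1 - spec$fst) / spec$fst
      p1 <- rbeta(1, q0[j] * sh, (1 - q0[j]) * sh)
      p2 <- rbeta(1, q0[j] * sh, (1 - q0[j]) * sh)
    } else {
      p1 <- p2 <- q0[j]
    }
    p <- ifelse(pop == 1L, p1, p2)
    rbinom(n, 2L, pmin(p, 0.999))
  }
  d <- matrix(0L, n, n_snps)
  for (j in seq_len(n_snps)) {
    col <- draw_col(j)
    tries <- 0
    while ((sum(col) == 0 || sum(col) == 2 * n) && tries < 100) {
      col <- draw_col(j)
      tries <- tries + 1
    }
    if (sum(col) == 0 || sum(col) == 2 * n) {
      stop("could not draw a polymorphic SNP; widen maf_range or enlarge ",
           "the cohort")
    }
    d[, j] <- col
  }
  af <- colMeans(d) / 2
  flip <- af > 0.5
  if (any(flip)) d[, flip] <- 2L - d[, flip, drop = FALSE]

  chrom_of_gene <- rep(seq_len(min(spec$n_chromosomes, spec$n_genes)),
                       length.out = spec$n_genes)
  chrom_of_gene <- sort(chrom_of_gene)
  chrom <- sprintf("%02d", chrom_of_gene[gene_of_snp])
  pos <- integer(n_snps)
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    pos[ii] <- seq_along(ii) * 1000L
  }
  genes <- sprintf("GENE%03d", gene_of_snp)
  snp_ids <- sprintf("SNP%05d", seq_len(n_snps))
  nonsyn <- runif(n_snps) <= spec$prop_nonsyn

  # causal variants: the first n_causal[g] nonsynonymous SNPs of gene g
  beta <- numeric(n_snps)
  for (g in seq_len(spec$n_genes)) {
    if (n_causal[g] > 0) {
      cand <- which(gene_of_snp == g & nonsyn)
      if (length(cand) < n_causal[g]) {
        stop("gene ", g, " has too few nonsynonymous SNPs for the ",
             "requested causal count")
      }
      beta[cand[seq_len(n_causal[g])]] <- spec$effect_size
    }
  }

  age <- round(rnorm(n, 50, 10))
  sex <- rbinom(n, 1, 0.5)
  smoking <- rbinom(n, 1, 0.3)
  ce <- spec$covariate_effects
  genetic <- drop(d %*% beta)
  shift <- spec$pop_trait_shift * (pop - 1.5) * 2 # -shift/2 vs +shift/2
  q1 <- genetic + ce$age * (age - 50) + ce$smoking * smoking + shift +
    rnorm(n, 0, spec$trait_noise_sd)
  q2 <- shift + rnorm(n, 0, spec$trait_noise_sd)
  q4 <- ce$age * (age - 50) + ce$sex * sex + ce$smoking * smoking + shift +
    rnorm(n, 0, spec$trait_noise_sd)
  lin <- -1 + 0.6 * scale(q1)[, 1] + 0.3 * scale(q2)[, 1] +
    0.3 * scale(q4)[, 1] + 0.4 * smoking + 0.01 * (age - 50)
  affected <- rbinom(n, 1, 1 / (1 + exp(-lin)))

  ids <- sprintf("IND%04d", seq_len(n))
  snps <- tibble(id = snp_ids, chromosome = chrom, position = pos,
                 gene = genes, is_nonsynonymous = nonsyn)
  g <- genotype_matrix(d, snps, ids)
  phen <- tibble(individual_id = ids, Q1 = q1, Q2 = q2, Q4 = q4,
                 Affected = affected, Age = as.numeric(age),
                 Sex = as.numeric(sex), Smoking = as.numeric(smoking),
                 population = pop)
  truth <- tibble(snp_id = snp_ids[beta != 0],
                  gene = genes[beta != 0],
                  effect = beta[beta != 0])
  list(genotypes = g, phenotypes = phen, truth = truth)
}

#' Power and type-I accounting across replicates
#'
#' Tallies rejections of corrected per-window p-values across replicated
#' runs against a truth labelling of functional windows. Reports per-window
#' rejection rates (power for functional windows, type-I rate for
#' nonfunctional ones) and two aggregate type-I conventions: the mean
#' per-window rate and the pooled per-test rate
#' (total false rejections / (replicates x nonfunctional windows)).
#'
#' @param results Tibble with columns `replicate`, `window_id`, and the
#'   corrected p-value column named by `p_col`.
#' @param truth Tibble with columns `window_id` and logical `functional`.
#' @param alpha Rejection level (default 0.05).
#' @param p_col Corrected p-value column (default `"p_bonferroni"`).
#' @return A list of class `ws_power_eval`: `windows` (per-window tibble
#'   with `rejection_rate`), `summary` (tibble with `n_replicates`,
#'   `mean_power`, `type1_per_window`, `type1_per_test`).
#' @export
evaluate_power_typeI <- function(results, truth, alpha = 0.05,
                                 p_col = "p_bonferroni") {
  stopifnot(p_col %in% names(results),
            all(c("replicate", "window_id") %in% names(results)))
  reps <- unique(results$replicate)
  if (length(reps) == 0) stop("no replicates to evaluate")
  df <- dplyr::left_join(results, truth, by = "window_id")
  df$functional <- !is.na(df$functional) & df$functional
  df$reject <- df[[p_col]] < alpha
  win <- dplyr::summarise(dplyr::group_by(df, .data$window_id,
                                          .data$functional),
                          n_reps = dplyr::n(),
                          n_reject = sum(.data$reject),
                          rejection_rate = mean(.data$reject),
                          .groups = "drop")
  nonf <- win[!win$functional, ]
  func <- win[win$functional, ]
  summary <- tibble(
    n_replicates = length(reps),
    mean_power = if (nrow(func)) mean(func$rejection_rate) else NA_real_,
    type1_per_window = if (nrow(nonf)) mean(nonf$rejection_rate) else
      NA_real_,
    type1_per_test = if (nrow(nonf)) sum(nonf$n_reject) / sum(nonf$n_reps)
      else NA_real_
  )
  structure(list(windows = win, summary = summary), class = "ws_power_eval")
}

#' @export
print.ws_power_eval <- function(x, ...) {
  cat("power / type-I evaluation\n")
  print(x$summary)
  invisible(x)
}
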