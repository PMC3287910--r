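# Windowed multilocus score statistic on denoised weighted genotypes,
# permutation-based empirical p-values, and two family-wise corrections.
#
# For a window of m centred columns X (n individuals) and a mean-zero
# residual trait Y:
#   U_j = sum_i X_ij Y_i            per-SNP score
#   V_j = (sum_i Y_i^2 / (n-1)) * sum_i X_ij^2
#   V   = sqrt(sum_j V_j)
#   T   = sum_j U_j / V             (0 when V = 0)
# Under permutation of Y both sum(Y^2) and the column norms are invariant,
# so T for every permutation is a single inner product with the window's
# row-sum vector; the whole permutation scan is one matrix product.

#' Centre window columns
#'
#' Subtracts each SNP column's mean across individuals (default) so that
#' per-SNP scores are mean-zero under permutation. The alternative
#' orientation (centring each individual's row across the window's
#' positions) is available for comparison.
#'
#' @param xw Numeric matrix, individuals x SNPs.
#' @param center `"individuals"` (centre each column) or `"positions"`
#'   (centre each row).
#' @return Centred matrix of the same dimension.
#' @export
center_window <- function(xw, center = c("individuals", "positions")) {
  center <- match.arg(center)
  xw <- as.matrix(xw)
  if (nrow(xw) < 2) stop("need at least 2 individuals")
  if (center == "individuals") {
    sweep(xw, 2, colMeans(xw), "-")
  } else {
    sweep(xw, 1, rowMeans(xw), "-")
  }
}

#' Multilocus score statistic of a window
#'
#' @param xc Centred weighted-genotype matrix for the window (n x m).
#' @param y Mean-zero residual trait of length n (a `ws_residual` or a
#'   numeric vector).
#' @return List with `U` (length m), `V_j` (length m), `V`, and `T`.
#' @export
score_statistic <- function(xc, y) {
  if (inherits(y, "ws_residual")) y <- y$values
  xc <- as.matrix(xc)
  n <- nrow(xc)
  if (length(y) != n) stop("trait length does not match genotype rows")
  U <- drop(crossprod(xc, y))
  V_j <- (sum(y^2) / (n - 1)) * colSums(xc^2)
  V <- sqrt(sum(V_j))
  T_stat <- if (V > 0) sum(U) / V else 0
  list(U = U, V_j = V_j, V = V, T = T_stat)
}

#' Collapsing (burden) comparator statistic
#'
#' Sums each individual's weighted genotypes across the window — the first
#' Fourier coefficient of the multilocus genotype, i.e. the classical
#' collapsing test — and computes the one-dimensional score statistic on the
#' centred sum.
#'
#' @param xw Weighted-genotype matrix for the window (not yet centred).
#' @param y Mean-zero residual trait.
#' @return List as in [score_statistic()] with m = 1.
#' @export
burden_statistic <- function(xw, y) {
  s <- rowSums(as.matrix(xw))
  score_statistic(center_window(matrix(s, ncol = 1)), y)
}

# generate a matrix of permuted traits (columns) deterministically
permute_traits <- function(y, m) {
  n <- length(y)
  vapply(seq_len(m), function(s) y[sample.int(n)], numeric(n))
}

#' Permutation p-value for one window
#'
#' Permutes the residual trait across individuals with the genotypes fixed
#' and compares `|T|` (or `T` one-sided) against the permuted statistics.
#' The default convention is the add-one estimator
#' `p = (1 + #permuted >= observed) / (M + 1)`, which is a valid p-value and
#' never exactly zero; `convention = "proportion"` gives the plain
#' `#permuted > observed / M` rank.
#'
#' @param xw Weighted-genotype window matrix (will be centred).
#' @param y Residual trait.
#' @param n_permutations Number of permutations M (default 60000).
#' @param seed RNG seed (required for reproducibility).
#' @param two_sided Compare absolute statistics (default `TRUE`).
#' @param convention `"add_one"` or `"proportion"`.
#' @return Scalar p-value.
#' @export
permutation_pvalue <- function(xw, y, n_permutations = 60000, seed = 1,
                               two_sided = TRUE,
                               convention = c("add_one", "proportion")) {
  convention <- match.arg(convention)
  if (n_permutations < 1) stop("need at least one permutation")
  if (inherits(y, "ws_residual")) y <- y$values
  xc <- center_window(xw)
  res <- window_perm_test(xc, list(seq_len(ncol(xc))), y,
                          n_permutations = n_permutations, seed = seed,
                          two_sided = two_sided, convention = convention,
                          maxstat = FALSE)
  res$p_empirical[1]
}

#' Bonferroni correction
#'
#' @param p_empirical Empirical p-value(s).
#' @param n_tests Number of windows (or genes) tested.
#' @return `min(1, p_empirical * n_tests)`, vectorised.
#' @export
bonferroni_correct <- function(p_empirical, n_tests) {
  stopifnot(n_tests >= 1)
  pmin(1, p_empirical * n_tests)
}

# Joint permutation scan over a list of windows sharing one set of trait
# permutations. Returns observed statistics, empirical p-values, and (when
# maxstat = TRUE) the global max-statistic p-values computed from the same
# permutation draws.
window_perm_test <- function(xc, snp_indices, y, n_permutations, seed,
                             two_sided = TRUE,
                             convention = "add_one",
                             maxstat = FALSE, chunk_size = 2000) {
  n <- nrow(xc)
  W <- length(snp_indices)
  if (W == 0) stop("no windows to test")
  S <- vapply(snp_indices,
              function(jj) rowSums(xc[, jj, drop = FALSE]), numeric(n))
  ssq <- vapply(snp_indices,
                function(jj) sum(xc[, jj, drop = FALSE]^2), numeric(1))
  sumy2 <- sum(y^2)
  V <- sqrt(sumy2 / (n - 1) * ssq)
  T_obs <- ifelse(V > 0, drop(crossprod(S, y)) / V, 0)
  crit <- if (two_sided) abs(T_obs) else T_obs
  count <- numeric(W)
  count_max <- numeric(W)
  set.seed(seed)
  done <- 0
  while (done < n_permutations) {
    m <- min(chunk_size, n_permutations - done)
    Yp <- permute_traits(y, m)
    Tp <- crossprod(S, Yp)
    Tp <- sweep(Tp, 1, pmax(V, .Machine$double.eps), "/")
    Tp[V <= 0, ] <- 0
    if (two_sided) Tp <- abs(Tp)
    if (convention == "add_one") {
      count <- count + rowSums(Tp >= crit)
    } else {
      count <- count + rowSums(Tp > crit)
    }
    if (maxstat) {
      mx <- apply(Tp, 2, max)
      if (convention == "add_one") {
        count_max <- count_max + vapply(crit, function(tt) sum(mx >= tt),
                                        numeric(1))
      } else {
        count_max <- count_max + vapply(crit, function(tt) sum(mx > tt),
                                        numeric(1))
      }
    }
    done <- done + m
  }
  M <- n_permutations
  p_emp <- if (convention == "add_one") (1 + count) / (M + 1) else count / M
  out <- list(T = T_obs, V = V, p_empirical = p_emp)
  if (maxstat) {
    out$p_maxstat <- if (convention == "add_one") {
      (1 + count_max) / (M + 1)
    } else {
      count_max / M
    }
  }
  out
}

#' Max-statistic global p-value
#'
#' Compares a window's statistic to the permutation distribution of the
#' genome-wide maximum `|T|` across all windows, reusing one shared set of
#' trait permutations. Valid family-wise control only when all windows share
#' a null distribution; with heterogeneous nulls its power collapses (the
#' motivation for the per-window Bonferroni route).
#'
#' @param xc Centred genotype matrix covering all windows.
#' @param snp_indices List of integer column-index vectors, one per window.
#' @param y Residual trait.
#' @param n_permutations,seed,two_sided As in [permutation_pvalue()].
#' @return Tibble with `T`, `p_empirical`, `p_maxstat` per window.
#' @export
maxstat_global_pvalue <- function(xc, snp_indices, y,
                                  n_permutations = 60000, seed = 1,
                                  two_sided = TRUE) {
  if (inherits(y, "ws_residual")) y <- y$values
  res <- window_perm_test(xc, snp_indices, y, n_permutations, seed,
                          two_sided = two_sided, maxstat = TRUE)
  tibble(T = res$T, p_empirical = res$p_empirical,
         p_maxstat = res$p_maxstat)
}

#' Single-SNP score scan (comparator)
#'
#' Per-SNP score statistics with normal-approximation p-values and a
#' Bonferroni correction across SNPs; the conventional one-SNP-at-a-time
#' baseline against which the windowed test is compared.
#'
#' @param xc Centred (weighted, adjusted) genotype matrix.
#' @param y Residual trait.
#' @return Tibble with `snp` (column index), `T`, `p`, `p_bonferroni`.
#' @export
single_snp_scan <- function(xc, y) {
  if (inherits(y, "ws_residual")) y <- y$values
  xc <- as.matrix(xc)
  n <- nrow(xc)
  U <- drop(crossprod(xc, y))
  V_j <- (sum(y^2) / (n - 1)) * colSums(xc^2)
  T_j <- ifelse(V_j > 0, U / sqrt(V_j), 0)
  p <- 2 * pnorm(-abs(T_j))
  tibble(snp = seq_len(ncol(xc)), T = T_j, p = p,
         p_bonferroni = pmin(1, p * ncol(xc)))
}
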