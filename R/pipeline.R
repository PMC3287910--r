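# End-to-end pipeline: orient/filter -> weight -> PC adjust -> residualize
# -> wavelet denoise -> window -> permutation score test -> corrections.

#' Pipeline configuration
#'
#' All tunable settings of [ws_run()] in one place. Defaults follow the
#' package's reference analysis: windows of 8 consecutive nonsynonymous
#' SNPs, automatic eigenvalue-gap choice of the number of stratification
#' components, Haar wavelet with level-dependent empirical Bayes
#' thresholding, 60,000 permutations, and per-window Bonferroni correction.
#'
#' @param window_mode `"fixed"` (blocks of `window_size` consecutive SNPs)
#'   or `"gene"` (all eligible SNPs of a gene).
#' @param window_size Fixed-mode window size, default 8.
#' @param nonsyn_only Test only nonsynonymous SNPs (default `TRUE`).
#' @param pca_k `"auto"` (eigenvalue-gap heuristic, see
#'   [select_num_components()]) or an integer number of components; 0
#'   disables the adjustment.
#' @param pca_ratio_threshold Gap factor for the automatic choice.
#' @param wavelet A [wavelet_config()].
#' @param wavelet_scope Denoise each individual's profile per
#'   `"chromosome"` (default) or per `"window"`.
#' @param n_permutations Permutations M for empirical p-values.
#' @param seed RNG seed for the permutation draws.
#' @param correction `"bonferroni"`, `"maxstat"`, or `"both"`.
#' @param two_sided Reject on `|T|` (default `TRUE`).
#' @param link `"identity"` (default; traits enter as linear-model
#'   residuals, including the binary trait) or `"logit"` (a 0/1 trait is
#'   residualised by a logistic fit on the adjusted predictors).
#' @param center Column-centring orientation, see [center_window()].
#' @return A list of class `ws_config`.
#' @export
ws_config <- function(window_mode = c("fixed", "gene"), window_size = 8,
                      nonsyn_only = TRUE, pca_k = "auto",
                      pca_ratio_threshold = 2,
                      wavelet = wavelet_config(),
                      wavelet_scope = c("chromosome", "window"),
                      n_permutations = 60000, seed = 1,
                      correction = c("bonferroni", "maxstat", "both"),
                      two_sided = TRUE, link = c("identity", "logit"),
                      center = c("individuals", "positions")) {
  structure(list(
    window_mode = match.arg(window_mode),
    window_size = window_size,
    nonsyn_only = isTRUE(nonsyn_only),
    pca_k = pca_k,
    pca_ratio_threshold = pca_ratio_threshold,
    wavelet = wavelet,
    wavelet_scope = match.arg(wavelet_scope),
    n_permutations = n_permutations,
    seed = seed,
    correction = match.arg(correction),
    two_sided = isTRUE(two_sided),
    link = match.arg(link),
    center = match.arg(center)
  ), class = "ws_config")
}

#' Windowed wavelet score test, end to end
#'
#' Runs the full analysis on a genotype matrix and an aligned phenotype
#' table: restricts to nonsynonymous SNPs, weights dosages by
#' `1/sqrt(n q (1-q))`, projects the top principal components out of
#' genotypes, trait, and covariates, residualises the trait on the given
#' predictors, denoises each individual's weighted multilocus profile by
#' wavelet shrinkage, forms windows, and computes permutation p-values for
#' the multilocus score statistic with the requested family-wise
#' correction(s).
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes Aligned phenotype tibble from [read_phenotypes()] (or
#'   any data frame with `individual_id` first); row order must match the
#'   genotype rows, or carry the `genotype_rows` attribute set by the
#'   reader.
#' @param trait Name of the trait column to test.
#' @param predictors Character vector of phenotype columns to residualise
#'   the trait on (covariates and/or other traits), or `NULL`.
#' @param config A [ws_config()].
#' @return A tibble of class `ws_result`, one row per window, with columns
#'   `window_id`, `chromosome`, `label`, `first_snp`, `last_snp`, `genes`,
#'   `n_snps`, `T`, `p_empirical`, `p_bonferroni` and/or `p_maxstat`,
#'   `n_permutations`; attributes carry the configuration, the selected
#'   number of components, and stage-by-stage counts.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_individuals = 120, n_genes = 12,
#'                                    n_causal_per_gene = c(4, rep(0, 11)),
#'                                    seed = 7))
#' res <- ws_run(sim$genotypes, sim$phenotypes, trait = "Q1",
#'               predictors = c("Age", "Smoking"),
#'               config = ws_config(window_mode = "gene",
#'                                  n_permutations = 199, seed = 7))
#' head(tidy(res))
#' @export
ws_run <- function(genotypes, phenotypes, trait, predictors = NULL,
                   config = ws_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "ws_config"))
  g_rows <- attr(phenotypes, "genotype_rows")
  if (!is.null(g_rows) && length(g_rows) != nrow(genotypes$dosages)) {
    genotypes <- subset_individuals(genotypes, g_rows)
  }
  if (nrow(phenotypes) != nrow(genotypes$dosages)) {
    stop("phenotype rows do not match genotype individuals; ",
         "align with read_phenotypes() first")
  }
  if (!trait %in% names(phenotypes)) stop("trait column not found: ", trait)
  log <- list(n_individuals = nrow(genotypes$dosages),
              n_snps_input = ncol(genotypes$dosages))

  snps <- genotypes$snps
  keep <- if (config$nonsyn_only) which(snps$is_nonsynonymous) else
    seq_len(nrow(snps))
  if (length(keep) == 0) stop("no nonsynonymous SNPs to test")
  d <- genotypes$dosages[, keep, drop = FALSE]
  snps <- snps[keep, , drop = FALSE]
  log$n_snps_tested <- ncol(d)

  q <- compute_maf(d)
  xw <- weight_genotypes(d, q)

  # stratification adjustment
  k <- config$pca_k
  n_fit <- if (identical(k, "auto")) 10L else as.integer(k)
  n_fit <- min(n_fit, nrow(d) - 1L, ncol(d))
  pca <- fit_genotype_pca(d, n_components = n_fit)
  if (identical(k, "auto")) {
    k <- select_num_components(pca$eigenvalues, config$pca_ratio_threshold)
    k <- min(k, pca$k)
  } else {
    k <- as.integer(k)
  }
  adj <- structure(list(C = pca$C[, seq_len(k), drop = FALSE],
                        eigenvalues = pca$eigenvalues, k = k),
                   class = "ws_pca")
  log$pca_k <- k
  xw <- pc_adjust(xw, adj)

  pred <- NULL
  if (!is.null(predictors) && length(predictors)) {
    miss <- setdiff(predictors, names(phenotypes))
    if (length(miss)) stop("predictor column(s) not found: ",
                           paste(miss, collapse = ", "))
    pred <- pc_adjust(as.matrix(phenotypes[predictors]), adj)
  }
  if (config$link == "logit") {
    # logistic fit needs the raw 0/1 status; predictors are adjusted
    y <- residualize_trait(as.numeric(phenotypes[[trait]]), pred,
                           name = trait, method = "logistic")
  } else {
    y_raw <- pc_adjust(as.numeric(phenotypes[[trait]]), adj)
    y <- residualize_trait(y_raw, pred, name = trait)
  }

  # denoise each individual's weighted profile
  xd <- xw
  if (config$wavelet_scope == "chromosome") {
    for (chr in unique(snps$chromosome)) {
      jj <- which(snps$chromosome == chr)
      if (length(jj) >= 2) {
        xd[, jj] <- denoise_matrix(xw[, jj, drop = FALSE], config$wavelet)
      }
    }
  }

  windows <- make_windows(snps, mode = config$window_mode,
                          size = config$window_size,
                          nonsyn_only = FALSE) # already filtered above
  log$n_windows <- nrow(windows)

  if (config$wavelet_scope == "window") {
    for (jj in windows$snp_indices) {
      xd[, jj] <- denoise_matrix(xw[, jj, drop = FALSE], config$wavelet)
    }
  }

  xc <- center_window(xd, center = config$center)
  res <- window_perm_test(xc, windows$snp_indices, y$values,
                          n_permutations = config$n_permutations,
                          seed = config$seed,
                          two_sided = config$two_sided,
                          maxstat = config$correction %in%
                            c("maxstat", "both"))
  log$n_permutations <- config$n_permutations

  first <- vapply(windows$snp_indices, function(jj)
    snps$position[jj[1]], numeric(1))
  last <- vapply(windows$snp_indices, function(jj)
    snps$position[jj[length(jj)]], numeric(1))
  genes <- vapply(windows$snp_indices, function(jj) {
    gg <- unique(snps$gene[jj])
    paste(gg[gg != "" & !is.na(gg)], collapse = ";")
  }, character(1))

  out <- tibble(
    window_id = windows$window_id,
    chromosome = windows$chromosome,
    label = windows$label,
    first_snp = as.integer(first),
    last_snp = as.integer(last),
    genes = genes,
    n_snps = windows$size,
    snp_indices = windows$snp_indices,
    T = res$T,
    p_empirical = res$p_empirical
  )
  if (config$correction %in% c("bonferroni", "both")) {
    out$p_bonferroni <- bonferroni_correct(out$p_empirical, nrow(out))
  }
  if (config$correction %in% c("maxstat", "both")) {
    out$p_maxstat <- res$p_maxstat
  }
  out$n_permutations <- config$n_permutations

  attr(out, "config") <- config
  attr(out, "log") <- log
  attr(out, "pca") <- adj
  attr(out, "provenance") <- list(
    seed = config$seed,
    n_permutations = config$n_permutations,
    correction = config$correction,
    window_mode = config$window_mode,
    window_size = config$window_size,
    pca_k = k,
    trait = trait
  )
  class(out) <- c("ws_result", class(out))
  out
}

#' @export
tidy.ws_result <- function(x, ...) {
  out <- x[, setdiff(names(x), "snp_indices")]
  class(out) <- setdiff(class(out), "ws_result")
  out
}

#' @export
glance.ws_result <- function(x, ...) {
  pcol <- if ("p_bonferroni" %in% names(x)) "p_bonferroni" else "p_maxstat"
  tibble(
    n_windows = nrow(x),
    n_snps = sum(x$n_snps),
    n_individuals = attr(x, "log")$n_individuals,
    pca_k = attr(x, "log")$pca_k,
    n_permutations = x$n_permutations[1],
    min_p_empirical = min(x$p_empirical),
    n_significant = sum(x[[pcol]] < 0.05),
    top_window = x$window_id[which.min(x$p_empirical)]
  )
}

#' Manhattan-style plot of windowed results
#'
#' @param object A `ws_result` from [ws_run()].
#' @param alpha Significance level drawn as a reference line on the
#'   corrected scale (default 0.05).
#' @param ... Unused.
#' @return A ggplot object: `-log10` empirical p-value per window, coloured
#'   by chromosome, with the Bonferroni-adjusted threshold line.
#' @export
autoplot.ws_result <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$index <- seq_len(nrow(df))
  thr <- alpha / nrow(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index,
                                   y = -log10(.data$p_empirical),
                                   colour = .data$chromosome)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2) +
    ggplot2::labs(x = "window (genome order)",
                  y = expression(-log[10] ~ "empirical p"),
                  title = "Windowed wavelet score test") +
    ggplot2::theme_minimal()
}

#' @export
print.ws_result <- function(x, ...) {
  cat(sprintf("wavescore result: %d windows, %d permutations, seed %s\n",
              nrow(x), x$n_permutations[1],
              format(attr(x, "config")$seed)))
  NextMethod()
}
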