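# MAF estimation and weighting, principal-component stratification
# adjustment, trait residualization, and window construction.

#' Estimated minor allele frequencies
#'
#' `q_j = sum(dosages[, j]) / (2 n)`. Dosages must already be oriented to the
#' minor allele, so every `q_j` lies in `(0, 0.5]`; a monomorphic column
#' (q = 0) indicates an upstream filtering failure and is an error.
#'
#' @param g A [genotype_matrix()] or a dosage matrix (individuals x SNPs).
#' @return Numeric vector of frequencies, one per SNP.
#' @export
compute_maf <- function(g) {
  d <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  n <- nrow(d)
  q <- colSums(d) / (2 * n)
  if (any(q == 0)) {
    stop("internal consistency error: monomorphic SNP reached compute_maf(); ",
         "monomorphic columns must be dropped upstream")
  }
  if (any(q > 0.5 + 1e-12)) {
    stop("dosages are not oriented to the minor allele (some q > 0.5)")
  }
  unname(q)
}

#' Frequency-weight a genotype matrix
#'
#' Divides each dosage column by `sqrt(n q (1 - q))`, up-weighting rare
#' alleles so that rare functional variants are not drowned by more common
#' neighbours.
#'
#' @param g A [genotype_matrix()] or dosage matrix.
#' @param q Minor allele frequencies from [compute_maf()]. Recomputed when
#'   missing.
#' @return Real matrix of weighted genotypes (individuals x SNPs).
#' @export
weight_genotypes <- function(g, q = NULL) {
  d <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  if (nrow(d) < 2) stop("need at least 2 individuals")
  if (is.null(q)) q <- compute_maf(d)
  stopifnot(length(q) == ncol(d))
  if (any(q <= 0 | q >= 1)) stop("undefined weight: q must be in (0, 1)")
  sweep(d, 2, sqrt(nrow(d) * q * (1 - q)), "/")
}

#' Principal components of the genotype matrix
#'
#' Eigendecomposition of the individual-by-individual covariance of
#' column-standardised dosages (each SNP centred at its mean and scaled by
#' `sqrt(q(1-q))`, the usual convention for stratification PCA). The leading
#' eigenvectors separate subpopulations and are used to project structure
#' out of genotypes, traits, and covariates.
#'
#' @param g A [genotype_matrix()] or dosage matrix.
#' @param n_components Number of component vectors to retain in `C`.
#' @return A list of class `ws_pca` with `C` (n x k, orthonormal columns),
#'   `eigenvalues` (all, descending), and `k`.
#' @export
fit_genotype_pca <- function(g, n_components = 10) {
  d <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  n <- nrow(d)
  p <- ncol(d)
  stopifnot(n_components >= 0, n_components <= min(n - 1, p))
  mu <- colMeans(d)
  q <- mu / 2
  s <- sqrt(q * (1 - q))
  s[s == 0] <- 1
  Zs <- sweep(sweep(d, 2, mu, "-"), 2, s, "/")
  M <- tcrossprod(Zs) / p
  ev <- eigen(M, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  rank_tol <- max(vals) * 1e-10 + 1e-300
  eff_rank <- sum(vals > rank_tol)
  if (n_components > eff_rank) {
    stop(sprintf("requested %d components but input has rank %d",
                 n_components, eff_rank))
  }
  C <- ev$vectors[, seq_len(n_components), drop = FALSE]
  structure(list(C = C, eigenvalues = vals, k = n_components),
            class = "ws_pca")
}

#' Choose the number of stratification components
#'
#' Heuristic gap rule: `k` is the largest index `j` such that
#' `ev[j]/ev[j+1] >= ratio_threshold` or
#' `ev[j] >= ratio_threshold * median(ev[(j+1):end])`. Returns 0 when no gap
#' is found (e.g. a flat spectrum). An explicit user choice of `k` always
#' overrides this heuristic in the pipeline.
#'
#' @param eigenvalues Numeric vector, descending.
#' @param ratio_threshold Gap factor, default 2.
#' @return Integer `k >= 0`.
#' @export
select_num_components <- function(eigenvalues, ratio_threshold = 2) {
  stopifnot(length(eigenvalues) >= 2)
  m <- length(eigenvalues)
  k <- 0L
  for (j in seq_len(m - 1L)) {
    rest <- eigenvalues[(j + 1L):m]
    if (eigenvalues[j + 1L] > 0 &&
        eigenvalues[j] / eigenvalues[j + 1L] >= ratio_threshold) {
      k <- j
    } else if (eigenvalues[j] >= ratio_threshold * median(rest) &&
               eigenvalues[j] > median(rest)) {
      k <- j
    }
  }
  k
}

#' Project structure out of a matrix or vector
#'
#' Returns `M - C (C' M)`: the residual of `M` after projecting onto the
#' span of the principal component vectors. The result is orthogonal to
#' every retained component, and the operation is idempotent. With `k = 0`
#' the input is returned unchanged.
#'
#' @param m Numeric matrix (rows = individuals) or vector of length n.
#' @param adj A `ws_pca` from [fit_genotype_pca()].
#' @return Adjusted object of the same shape as `m`.
#' @export
pc_adjust <- function(m, adj) {
  stopifnot(inherits(adj, "ws_pca"))
  vec <- is.null(dim(m))
  M <- if (vec) matrix(m, ncol = 1) else as.matrix(m)
  if (adj$k == 0) return(m)
  if (nrow(M) != nrow(adj$C)) stop("dimension mismatch in pc_adjust()")
  out <- M - adj$C %*% crossprod(adj$C, M)
  if (vec) drop(out) else out
}

#' Residualize a trait on covariates
#'
#' Ordinary least squares of `y` on `predictors` plus an intercept; the
#' residual vector is what enters the association test, so covariate and
#' secondary-trait influences are removed before testing. The binary
#' affection trait is residualised by the same linear fit by default (a
#' linear probability model); the projection is unique even when predictors
#' are collinear, in which case a warning is emitted and a pseudoinverse
#' fit is used.
#'
#' @param y Numeric trait vector (already stratification-adjusted; for
#'   `method = "logistic"` the raw 0/1 status).
#' @param predictors Numeric matrix of covariates / secondary traits (already
#'   stratification-adjusted), or `NULL` for an intercept-only fit.
#' @param name Trait name recorded on the result.
#' @param method `"ols"` (default) or `"logistic"` (response residuals
#'   `y - fitted` from a logistic fit; requires `y` in `{0, 1}`).
#' @return A list of class `ws_residual`: `values` (mean-zero residuals),
#'   `source_trait`, `model_terms`, `coefficients`.
#' @export
residualize_trait <- function(y, predictors = NULL, name = "trait",
                              method = c("ols", "logistic")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("non-finite trait values")
  X <- cbind(`(Intercept)` = rep(1, length(y)),
             if (!is.null(predictors)) as.matrix(predictors))
  qrX <- qr(X)
  if (method == "logistic") {
    if (!all(y %in% c(0, 1))) {
      stop("logistic residualization needs a 0/1 trait")
    }
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial())
    )
    fitted <- fit$fitted.values
    coefs <- fit$coefficients
  } else if (qrX$rank < ncol(X)) {
    warning("collinear predictors in residualize_trait(); using pseudoinverse")
    beta <- MASS::ginv(X) %*% y
    fitted <- drop(X %*% beta)
    coefs <- drop(beta)
  } else {
    fit <- lm.fit(X, y)
    fitted <- drop(fit$fitted.values)
    coefs <- fit$coefficients
  }
  structure(list(values = y - fitted,
                 source_trait = name,
                 model_terms = colnames(X)[-1] %||% character(),
                 coefficients = coefs),
            class = "ws_residual")
}

#' Build testing windows over nonsynonymous SNPs
#'
#' Fixed mode partitions the (optionally nonsynonymous-filtered) SNPs of
#' each chromosome into consecutive non-overlapping blocks of `size`; a
#' trailing partial block is kept when it has at least 2 SNPs. Gene mode
#' makes one window per gene from all its (nonsynonymous) SNPs; genes with
#' fewer than 2 such SNPs are skipped.
#'
#' @param snps Tibble of SNP records (columns `id`, `chromosome`, `position`,
#'   `gene`, `is_nonsynonymous`), genome-sorted; row numbers are the column
#'   indices of the corresponding genotype matrix.
#' @param mode `"fixed"` or `"gene"`.
#' @param size Window size for fixed mode (default 8).
#' @param nonsyn_only Restrict to nonsynonymous SNPs (default `TRUE`).
#' @return Tibble with columns `window_id`, `chromosome`, `label`,
#'   `snp_indices` (list of integer vectors indexing matrix columns), `size`.
#' @export
make_windows <- function(snps, mode = c("fixed", "gene"), size = 8,
                         nonsyn_only = TRUE) {
  mode <- match.arg(mode)
  stopifnot(size >= 1)
  idx_all <- seq_len(nrow(snps))
  keep <- if (nonsyn_only) which(snps$is_nonsynonymous) else idx_all
  if (length(keep) == 0) {
    stop("no SNPs survive the nonsynonymous filter; no windows can be built")
  }
  sub <- snps[keep, , drop = FALSE]
  rows <- list()
  if (mode == "fixed") {
    for (chr in unique(sub$chromosome)) {
      ii <- keep[sub$chromosome == chr]
      nb <- ceiling(length(ii) / size)
      for (b in seq_len(nb)) {
        block <- ii[((b - 1) * size + 1):min(b * size, length(ii))]
        if (length(block) < 2) {
          ws_msg("dropping trailing 1-SNP window on chromosome %s", chr)
          next
        }
        rows[[length(rows) + 1L]] <- tibble(
          chromosome = chr,
          label = sprintf("%s:%d-%d", chr, snps$position[block[1]],
                          snps$position[block[length(block)]]),
          snp_indices = list(block),
          size = length(block)
        )
      }
    }
  } else {
    genes <- unique(sub$gene[!is.na(sub$gene) & sub$gene != ""])
    for (gn in genes) {
      ii <- keep[sub$gene == gn & !is.na(sub$gene)]
      if (length(ii) < 2) {
        ws_msg("skipping gene %s with < 2 eligible SNPs", gn)
        next
      }
      rows[[length(rows) + 1L]] <- tibble(
        chromosome = snps$chromosome[ii[1]],
        label = gn,
        snp_indices = list(ii),
        size = length(ii)
      )
    }
  }
  if (length(rows) == 0) stop("no windows with >= 2 SNPs could be formed")
  out <- dplyr::bind_rows(rows)
  # genome order: by chromosome, then by first matrix column of the window
  ord <- order(out$chromosome, vapply(out$snp_indices, min, numeric(1)))
  out <- out[ord, ]
  out$window_id <- sprintf("W%04d", seq_len(nrow(out)))
  out[, c("window_id", "chromosome", "label", "snp_indices", "size")]
}
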