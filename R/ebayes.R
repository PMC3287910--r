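# Empirical Bayes posterior-median thresholding of wavelet coefficients.
#
# Model (on the noise-standardised scale): Z | u ~ N(u, 1) with prior
# u ~ (1 - w) delta_0 + w * Laplace(a). The mixing weight w is estimated by
# marginal maximum likelihood, coefficients are replaced by the posterior
# median of u given z, which is exactly zero whenever |z| <= t(w); t(w) is
# the induced threshold. All formulas below are closed-form in pnorm/qnorm
# and evaluated in log space for stability at large |z|.

# log marginal density of z under the Laplace(a) slab convolved with N(0,1)
log_g_laplace <- function(z, a) {
  lgp <- log(a / 2) + a^2 / 2 - a * z + pnorm(z - a, log.p = TRUE)
  lgn <- log(a / 2) + a^2 / 2 + a * z + pnorm(-z - a, log.p = TRUE)
  logsumexp2(lgp, lgn)
}

# log posterior probability that u > 0 given z (vectorised in z and w)
log_ppos_laplace <- function(z, w, a) {
  lphi <- dnorm(z, log = TRUE)
  lgp <- log(a / 2) + a^2 / 2 - a * z + pnorm(z - a, log.p = TRUE)
  lgn <- log(a / 2) + a^2 / 2 + a * z + pnorm(-z - a, log.p = TRUE)
  lg <- logsumexp2(lgp, lgn)
  lw <- ifelse(w > 0, log(w), -Inf)
  l1mw <- ifelse(w < 1, log1p(-w), -Inf)
  ld <- logsumexp2(l1mw + lphi, lw + lg)
  lw + lgp - ld
}

# posterior median on the standardised scale; z, w vectors (w recycled)
postmed_laplace <- function(z, w, a) {
  sgn <- sign(z)
  z <- abs(z)
  lp_pos <- log_ppos_laplace(z, w, a)
  med <- numeric(length(z))
  hit <- is.finite(lp_pos) & lp_pos > log(0.5)
  if (any(hit)) {
    zh <- z[hit]
    # solve P(u > t | z) = 1/2 inside the positive slab component:
    # Phi_bar(t - z + a) = Phi(z - a) / (2 * p_pos)
    lratio <- pnorm(zh - a, log.p = TRUE) - log(2) - lp_pos[hit]
    t_adj <- qnorm(lratio, lower.tail = FALSE, log.p = TRUE)
    med[hit] <- pmin(pmax(0, zh - a + t_adj), zh)
  }
  sgn * med
}

# marginal ML estimate of w for each row of a standardised coefficient
# matrix; the log-likelihood is concave in w, solved by bisection on its
# derivative
ebayes_weight_rows <- function(Z, a, tol = 1e-8) {
  Z <- as.matrix(Z)
  nr <- nrow(Z)
  lr <- log_g_laplace(Z, a) - dnorm(Z, log = TRUE) # log(g/phi) >= some -0.9
  E <- matrix(exp(-lr), nr) # phi/g, bounded above (~2.3 at z = 0)
  score <- function(w) {
    # d/dw sum log((1-w) phi + w g) = sum (1 - E) / ((1-w) E + w)
    Wm <- matrix(w, nr, ncol(E))
    rowSums((1 - E) / ((1 - Wm) * E + Wm))
  }
  w_hat <- rep(NA_real_, nr)
  s1 <- rowSums(1 - E)
  w_hat[s1 >= 0] <- 1
  s0 <- rowSums((1 - E) / E)
  w_hat[is.na(w_hat) & s0 <= 0] <- 0
  open <- which(is.na(w_hat))
  if (length(open)) {
    lo <- rep(0, length(open))
    hi <- rep(1, length(open))
    Eo <- E[open, , drop = FALSE]
    nro <- length(open)
    for (it in seq_len(60)) {
      mid <- (lo + hi) / 2
      Wm <- matrix(mid, nro, ncol(Eo))
      s <- rowSums((1 - Eo) / ((1 - Wm) * Eo + Wm))
      up <- s > 0
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
      if (max(hi - lo) < tol) break
    }
    w_hat[open] <- (lo + hi) / 2
  }
  w_hat
}

#' Estimate the wavelet-domain noise standard deviation
#'
#' Robust scale estimate from the finest-level detail coefficients:
#' `median(|d|) / 0.6745`, the usual wavelet-denoising convention.
#'
#' @param finest_details Numeric vector of finest-level detail coefficients.
#' @return Non-negative scalar. Zero is possible (e.g. all details zero);
#'   [denoise_matrix()] falls back to the standard deviation of all detail
#'   coefficients when that happens for a signal that still has nonzero
#'   details.
#' @export
estimate_noise_sd <- function(finest_details) {
  if (length(finest_details) == 0) stop("no detail coefficients")
  median(abs(finest_details)) / 0.6745
}

#' Marginal maximum-likelihood mixing weight
#'
#' Estimates the spike-and-slab mixing weight `w` by maximising the marginal
#' likelihood of observed coefficients `z` under
#' `Z ~ (1-w) N(0, sigma^2) + w (Laplace(a) * N(0, sigma^2))`.
#' The log-likelihood is concave in `w`; the maximiser on `[0, 1]` is found
#' by bisection on the derivative to tolerance 1e-6 or better.
#'
#' @param z Numeric vector of coefficients.
#' @param a Laplace slab scale on the standardised scale (default 0.5).
#' @param sigma Noise standard deviation (> 0).
#' @return Scalar `w` in `[0, 1]`.
#' @export
marginal_mle_weight <- function(z, a = 0.5, sigma = 1) {
  if (any(!is.finite(z))) stop("non-finite coefficients")
  stopifnot(sigma > 0, a > 0)
  ebayes_weight_rows(matrix(z / sigma, nrow = 1), a)
}

#' Spike-and-slab posterior description
#'
#' Bundles the mixing weight, slab scale, and noise level, together with the
#' induced threshold `t_of_w`: the posterior median of `u` given `z` is
#' exactly zero if and only if `|z| <= t_of_w`.
#'
#' @param w Mixing weight in `[0, 1]`.
#' @param a Laplace slab scale (> 0), standardised scale.
#' @param sigma Noise standard deviation (> 0).
#' @return A list of class `ws_posterior` with fields `w`, `a`, `sigma`,
#'   `t_of_w`.
#' @export
ebayes_posterior <- function(w, a = 0.5, sigma = 1) {
  stopifnot(w >= 0, w <= 1, a > 0, sigma > 0)
  structure(list(w = w, a = a, sigma = sigma,
                 t_of_w = threshold_value(w, a, sigma)),
            class = "ws_posterior")
}

#' Posterior median shrinkage of a coefficient
#'
#' The posterior median of the signal mean `u` given an observed coefficient
#' `z` under the spike-and-slab Laplace prior. Antisymmetric in `z`, never
#' larger than `|z|` in magnitude, and exactly zero whenever
#' `|z| <= post$t_of_w`.
#'
#' @param z Numeric vector of observed coefficients.
#' @param post An [ebayes_posterior()].
#' @return Shrunk coefficients, same length as `z`.
#' @export
posterior_median <- function(z, post) {
  stopifnot(inherits(post, "ws_posterior"))
  if (post$w == 0) return(numeric(length(z)))
  out <- post$sigma * postmed_laplace(z / post$sigma, post$w, post$a)
  out[abs(z) <= post$t_of_w] <- 0
  out
}

#' Threshold induced by the posterior median rule
#'
#' The smallest `|z|` at which the posterior median becomes nonzero, found by
#' bisection (tolerance 1e-8 on the standardised scale). Monotonically
#' nonincreasing in `w`; `w = 0` returns `Inf` (everything is thresholded),
#' `w = 1` returns 0 (pure slab).
#'
#' @param w Mixing weight in `[0, 1]`.
#' @param a Laplace slab scale (> 0).
#' @param sigma Noise standard deviation (> 0).
#' @return Non-negative scalar threshold on the scale of `z`.
#' @export
threshold_value <- function(w, a = 0.5, sigma = 1, tol = 1e-8) {
  stopifnot(w >= 0, w <= 1, a > 0, sigma > 0)
  if (w == 0) return(Inf)
  nonzero_at <- function(z) log_ppos_laplace(z, w, a) > log(0.5)
  lo <- 0
  hi <- 1
  while (!nonzero_at(hi)) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e6) return(Inf)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nonzero_at(mid)) hi <- mid else lo <- mid
  }
  sigma * (lo + hi) / 2
}

#' Denoise weighted multilocus genotype signals
#'
#' Applies the wavelet transform, level-dependent empirical Bayes
#' posterior-median thresholding of the detail coefficients (approximation
#' coefficients are never shrunk), and the inverse transform to each row of
#' `X`. Rows are treated independently: each individual's multilocus
#' genotype profile is denoised on its own, so a strong isolated signal
#' (a rare variant carried by few individuals) is not smoothed away by the
#' rest of the cohort.
#'
#' @param X Numeric matrix, individuals in rows, ordered positions in
#'   columns (at least 2 columns).
#' @param cfg A [wavelet_config()].
#' @return Matrix of the same dimension as `X`.
#' @export
denoise_matrix <- function(X, cfg = wavelet_config()) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("denoise needs signals of length >= 2")
  if (any(!is.finite(X))) stop("non-finite input")
  n <- ncol(X)
  p <- next_pow2(n)
  lev_max <- max_dwt_level(p, cfg$family)
  levels <- if (identical(cfg$max_level, "auto")) lev_max else
    min(as.integer(cfg$max_level), lev_max)
  op <- dwt_operator(p, cfg$family, levels)
  Z <- cbind(X, matrix(0, nrow(X), p - n)) %*% t(op$W)
  if (cfg$shrink == "none") {
    out <- Z %*% op$W
    return(out[, seq_len(n), drop = FALSE])
  }
  det_idx <- unlist(op$detail)
  finest <- op$detail[[levels]]
  if (identical(cfg$noise_sd, "mad")) {
    sigma <- apply(abs(Z[, finest, drop = FALSE]), 1, median) / 0.6745
  } else {
    sigma <- rep(cfg$noise_sd, nrow(X))
  }
  has_detail <- rowSums(Z[, det_idx, drop = FALSE]^2) > 0
  bad <- has_detail & sigma <= 0
  if (any(bad)) {
    ws_msg("noise MAD zero for %d signal(s); falling back to detail sd",
           sum(bad))
    sigma[bad] <- apply(Z[bad, det_idx, drop = FALSE], 1, sd)
  }
  act <- which(has_detail & sigma > 0)
  if (length(act)) {
    blocks <- if (cfg$level_dependent) op$detail else list(det_idx)
    for (ii in blocks) {
      Zs <- Z[act, ii, drop = FALSE] / sigma[act]
      w <- ebayes_weight_rows(Zs, cfg$prior_scale)
      shrunk <- postmed_laplace(as.vector(Zs),
                                rep(w, times = ncol(Zs)),
                                cfg$prior_scale)
      Z[act, ii] <- sigma[act] * matrix(shrunk, nrow = length(act))
    }
  }
  out <- Z %*% op$W
  out[, seq_len(n), drop = FALSE]
}

#' Denoise a single signal
#'
#' Vector convenience wrapper around [denoise_matrix()].
#'
#' @param x Numeric vector, length at least 2.
#' @param cfg A [wavelet_config()].
#' @return Numeric vector, same length as `x`.
#' @export
denoise_signal <- function(x, cfg = wavelet_config()) {
  drop(denoise_matrix(matrix(x, nrow = 1), cfg))
}
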