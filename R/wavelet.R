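# Orthogonal periodic discrete wavelet transform.
#
# Signals are zero-padded to the next power of two; each decomposition level
# applies a decimated circular filter pair (low/high) derived from an
# orthonormal scaling filter. The full multi-level analysis is materialised
# once per (length, family, depth) as an orthogonal matrix W (cached), so the
# transform of a whole cohort is a single matrix product and the inverse is
# multiplication by W itself (W' W = I).

wavelet_filters <- function(family = c("haar", "d4")) {
  family <- match.arg(family)
  switch(family,
    haar = c(1, 1) / sqrt(2),
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  )
}

#' Wavelet and thresholding configuration
#'
#' Settings for the per-individual denoising step: wavelet family,
#' decomposition depth, the Laplace slab scale of the spike-and-slab prior,
#' how the noise standard deviation is estimated, and whether the mixing
#' weight is estimated separately at each resolution level.
#'
#' @param family Scaling filter: `"haar"` (default; suited to the
#'   piecewise-constant profile of weighted genotype vectors) or `"d4"`
#'   (Daubechies 4-tap).
#' @param max_level Decomposition depth, or `"auto"` for the maximum depth
#'   the padded length and filter support allow.
#' @param prior_scale Scale `a > 0` of the Laplace slab, on the
#'   noise-standardised scale. Default 0.5.
#' @param noise_sd `"mad"` to estimate the noise standard deviation as
#'   `median(|finest details|)/0.6745`, or a fixed positive number.
#' @param level_dependent Estimate the mixing weight `w` per resolution
#'   level (default `TRUE`) rather than once over all detail coefficients.
#' @param shrink `"postmed"` applies posterior-median shrinkage;
#'   `"none"` disables shrinkage entirely (transform + inverse only).
#' @return A list of class `ws_wavelet_config`.
#' @export
wavelet_config <- function(family = "haar", max_level = "auto",
                           prior_scale = 0.5, noise_sd = "mad",
                           level_dependent = TRUE,
                           shrink = c("postmed", "none")) {
  stopifnot(prior_scale > 0)
  if (!identical(max_level, "auto")) {
    stopifnot(is.numeric(max_level), max_level >= 1)
  }
  if (!identical(noise_sd, "mad")) stopifnot(is.numeric(noise_sd), noise_sd > 0)
  structure(
    list(family = match.arg(family, c("haar", "d4")),
         max_level = max_level,
         prior_scale = prior_scale,
         noise_sd = noise_sd,
         level_dependent = isTRUE(level_dependent),
         shrink = match.arg(shrink)),
    class = "ws_wavelet_config"
  )
}

max_dwt_level <- function(padded_length, family) {
  h <- wavelet_filters(family)
  # keep every intermediate length >= filter support so the periodised
  # filter bank stays orthogonal
  max(1L, floor(log2(padded_length / length(h))) + 1L)
}

# one analysis level: circular decimated filtering, scalar reference version
dwt_step <- function(x, h) {
  n <- length(x)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  half <- n %/% 2L
  a <- numeric(half)
  d <- numeric(half)
  for (k in seq_len(half)) {
    ii <- ((2L * (k - 1L) + seq_along(h) - 1L) %% n) + 1L
    a[k] <- sum(h * x[ii])
    d[k] <- sum(g * x[ii])
  }
  list(a = a, d = d)
}

dwt_full <- function(x, h, levels) {
  a <- x
  details <- vector("list", levels) # details[[1]] = finest
  for (lev in seq_len(levels)) {
    s <- dwt_step(a, h)
    details[[lev]] <- s$d
    a <- s$a
  }
  list(a = a, details = details)
}

.dwt_cache <- new.env(parent = emptyenv())

# orthogonal analysis matrix and coefficient index blocks for padded length n
dwt_operator <- function(n, family, levels) {
  key <- paste(n, family, levels, sep = "|")
  hit <- .dwt_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- wavelet_filters(family)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- numeric(n)
    e[i] <- 1
    f <- dwt_full(e, h, levels)
    # layout: approximation, then details coarse -> fine
    W[, i] <- c(f$a, unlist(rev(f$details)))
  }
  la <- n / 2^levels
  blocks <- list(approx = seq_len(la))
  off <- la
  detail <- vector("list", levels) # coarse -> fine
  for (j in seq_len(levels)) {
    len <- n / 2^(levels - j + 1L)
    detail[[j]] <- off + seq_len(len)
    off <- off + len
  }
  out <- list(W = W, approx = blocks$approx, detail = detail)
  .dwt_cache[[key]] <- out
  out
}

#' Discrete wavelet transform of a signal
#'
#' Zero-pads `x` to the next power of two and decomposes it into an
#' approximation vector and detail vectors at each resolution level
#' (coarse to fine) using an orthogonal periodic filter bank.
#'
#' @param x Numeric vector, length at least 2.
#' @param cfg A [wavelet_config()].
#' @return A list of class `ws_pyramid` with elements `approximation`,
#'   `details` (list, coarse to fine), `original_length`, `padded_length`,
#'   `levels`, `family`.
#' @seealso [idwt()], [denoise_signal()]
#' @export
dwt <- function(x, cfg = wavelet_config()) {
  if (length(x) < 2) stop("dwt() needs a signal of length >= 2")
  if (any(!is.finite(x))) stop("dwt() requires finite input")
  p <- next_pow2(length(x))
  lev_max <- max_dwt_level(p, cfg$family)
  levels <- if (identical(cfg$max_level, "auto")) lev_max else
    min(as.integer(cfg$max_level), lev_max)
  op <- dwt_operator(p, cfg$family, levels)
  z <- drop(op$W %*% c(x, numeric(p - length(x))))
  structure(
    list(approximation = z[op$approx],
         details = lapply(op$detail, function(ii) z[ii]),
         original_length = length(x),
         padded_length = p,
         levels = levels,
         family = cfg$family),
    class = "ws_pyramid"
  )
}

#' Inverse discrete wavelet transform
#'
#' Reconstructs the signal from a coefficient pyramid and truncates to the
#' original (pre-padding) length. `idwt(dwt(x))` restores `x` to machine
#' precision.
#'
#' @param pyramid A `ws_pyramid` from [dwt()].
#' @return Numeric vector of length `pyramid$original_length`.
#' @export
idwt <- function(pyramid) {
  stopifnot(inherits(pyramid, "ws_pyramid"))
  op <- dwt_operator(pyramid$padded_length, pyramid$family, pyramid$levels)
  z <- c(pyramid$approximation, unlist(pyramid$details))
  drop(crossprod(op$W, z))[seq_len(pyramid$original_length)]
}
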