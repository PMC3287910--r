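# Independent oracles used to validate the closed-form implementations.

# posterior median by brute-force quadrature and CDF inversion under the
# spike-and-slab Laplace prior; shares only the model definition with the
# package's closed-form code
oracle_postmed <- function(z, w, a, sigma = 1) {
  zs <- z / sigma
  slab_d <- function(u) dnorm(zs - u) * (a / 2) * exp(-a * abs(u))
  hi <- abs(zs) + 40
  int <- function(l, u) {
    if (u <= l) return(0)
    integrate(slab_d, l, u, rel.tol = 1e-12, subdivisions = 400L)$value
  }
  slab_mass <- int(-hi, 0) + int(0, hi)
  D <- (1 - w) * dnorm(zs) + w * slab_mass
  p_pos <- w * int(0, hi) / D
  p_neg <- w * int(-hi, 0) / D
  if (p_pos <= 0.5 && p_neg <= 0.5) return(0)
  if (p_pos > 0.5) {
    f <- function(t) w * int(t, hi) / D - 0.5
    return(sigma * uniroot(f, c(0, hi - 1), tol = 1e-12)$root)
  }
  f <- function(t) w * int(-hi, t) / D - 0.5
  sigma * uniroot(f, c(-hi + 1, 0), tol = 1e-12)$root
}

# marginal log-likelihood of w with the slab marginal computed by numeric
# convolution (independent of the package's closed-form marginal)
oracle_loglik_w <- function(w, z, a, sigma = 1) {
  g1 <- vapply(z / sigma, function(zz) {
    integrate(function(u) dnorm(zz - u) * (a / 2) * exp(-a * abs(u)),
              -abs(zz) - 40, abs(zz) + 40, rel.tol = 1e-10)$value
  }, numeric(1))
  sum(log((1 - w) * dnorm(z / sigma) + w * g1))
}

# loop-based score statistic, no linear algebra shortcuts
oracle_score <- function(xc, y) {
  n <- nrow(xc)
  m <- ncol(xc)
  U <- numeric(m)
  V_j <- numeric(m)
  sy2 <- 0
  for (i in seq_len(n)) sy2 <- sy2 + y[i]^2
  for (j in seq_len(m)) {
    u <- 0
    sx2 <- 0
    for (i in seq_len(n)) {
      u <- u + xc[i, j] * y[i]
      sx2 <- sx2 + xc[i, j]^2
    }
    U[j] <- u
    V_j[j] <- sy2 / (n - 1) * sx2
  }
  V <- sqrt(sum(V_j))
  list(U = U, V_j = V_j, V = V, T = if (V > 0) sum(U) / V else 0)
}

# Kolmogorov-Smirnov distance to Uniform(0, 1)
ks_distance <- function(p) {
  n <- length(p)
  sp <- sort(p)
  max(abs(c(sp - (seq_len(n) - 1) / n, sp - seq_len(n) / n)))
}
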