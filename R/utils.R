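# internal helpers shared across modules

next_pow2 <- function(n) {
  stopifnot(n >= 1)
  as.integer(2^ceiling(log2(max(n, 2L))))
}

# elementwise log(exp(a) + exp(b)), safe for -Inf
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  both_ninf <- is.infinite(m) & m < 0
  out[both_ninf] <- -Inf
  out
}

ws_msg <- function(...) {
  if (isTRUE(getOption("wavescore.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

# small deterministic string hash (djb2 mod 2^31-1) for provenance headers
ws_hash <- function(x) {
  stopifnot(is.character(x))
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

is_binary01 <- function(x) all(x %in% c(0, 1))

# derive a stream of distinct 32-bit seeds from one master seed
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + 11 * seq_len(n)) %% 2147483629
}
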