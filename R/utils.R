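# Internal helpers: seeded evaluation without clobbering the caller's RNG
# state, structured error conditions, and FFT-based "same" convolution for
# complex reflectivity fields.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopCond <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "echomapError")))
}

# Linear convolution with 'same'-size output and zero padding, via FFT.
# x may be complex; k is a real kernel with odd dimensions.
convolveSame <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  Hp <- stats::nextn(H + kh - 1L, c(2L, 3L, 5L))
  Wp <- stats::nextn(W + kw - 1L, c(2L, 3L, 5L))
  xp <- matrix(0 + 0i, Hp, Wp); xp[seq_len(H), seq_len(W)] <- x
  kp <- matrix(0, Hp, Wp); kp[seq_len(kh), seq_len(kw)] <- k
  full <- stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE) / (Hp * Wp)
  r0 <- (kh - 1L) %/% 2L
  c0 <- (kw - 1L) %/% 2L
  full[r0 + seq_len(H), c0 + seq_len(W)]
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
deriveSeeds <- function(masterSeed, n) {
  withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
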