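# Independent slow-path oracles, deliberately written with scalar loops so
# they share no code with the vectorized implementation.

slow_update <- function(J, s) {
  N <- length(s)
  out <- numeric(N)
  for (i in 1:N) {
    h <- 0
    for (j in 1:N) h <- h + J[i, j] * s[j]
    out[i] <- if (h >= 0) 1 else -1
  }
  out
}

# Exact one-step bit-error probability by direct enumeration with loops.
slow_exhaustive_bit_error <- function(N, P, retain_diagonal) {
  nb <- N * P
  total <- 0
  for (k in 0:(2^nb - 1)) {
    bits <- as.integer(intToBits(k))[1:nb]
    X <- matrix(2 * bits - 1, nrow = P, ncol = N)
    J <- matrix(0, N, N)
    for (i in 1:N) for (j in 1:N) {
      J[i, j] <- sum(X[, i] * X[, j]) / P
    }
    if (!retain_diagonal) diag(J) <- 0
    for (mu in 1:P) {
      out <- slow_update(J, X[mu, ])
      total <- total + sum(out != X[mu, ])
    }
  }
  total / (2^nb * N * P)
}

expect_close <- function(x, y, tol) {
  expect_true(abs(x - y) <= tol,
              label = sprintf("|%g - %g| <= %g", x, y, tol))
}
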