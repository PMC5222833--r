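# Internal helpers shared across the package.

# Deterministic seed folding: combines an experiment seed with stream
# identifiers (replicate index, grid coordinates, convention flag) into a
# set.seed()-able integer. Multiplicative-congruential fold; all arithmetic in
# doubles, well below 2^53, result strictly below 2^31.
derive_seed <- function(seed, ...) {
  m <- 2147483563
  h <- as.numeric(seed) %% m
  for (x in c(...)) {
    h <- (h * 69069 + as.numeric(x) + 1) %% m
  }
  as.integer(h)
}

# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# m x n matrix of independent fair +/-1 spins (double storage, for BLAS).
rand_spin_matrix <- function(m, n) {
  matrix(2 * (stats::runif(m * n) < 0.5) - 1, nrow = m, ncol = n)
}

# sign with the package-wide convention sign(0) = +1, so the synchronous
# dynamics is fully deterministic.
sign0 <- function(x) {
  ifelse(x >= 0, 1, -1)
}

is_spin_vector <- function(s) {
  is.numeric(s) && length(s) >= 1L && all(s == 1 | s == -1)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.numeric(x)
}

# 95% Wilson score interval half-width for a binomial proportion; valid near 0.
wilson_halfwidth <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  (z / (n + z^2)) * sqrt(k * (n - k) / n + z^2 / 4)
}

# Condition constructors: the CLI maps these onto exit statuses.
resource_error <- function(msg) {
  stop(structure(class = c("hopcapacity_resource_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

usage_error <- function(msg) {
  stop(structure(class = c("hopcapacity_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Spin states print as '+'/'-' strings in logs and show methods.
format_spins <- function(s) {
  paste(ifelse(s > 0, "+", "-"), collapse = "")
}
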