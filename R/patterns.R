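#' Generate a random training set of binary patterns
#'
#' Draws `P` patterns of `N` spins, each entry an independent fair draw from
#' \{-1, +1\}. These are the memories later encoded into a Hebbian coupling
#' matrix. Sampling is with replacement over the \eqn{2^N} possible states, so
#' duplicate patterns are permitted (and counted independently in all error
#' statistics).
#'
#' @param P Number of patterns (rows).
#' @param N Number of neurons (columns).
#' @param seed Optional integer seed. When supplied, generation is
#'   deterministic and the caller's RNG stream is left untouched.
#' @return A `P x N` matrix of class `"pattern_set"` with entries in
#'   \{-1, +1\} and attributes `n_patterns`, `n_neurons` and `seed`.
#' @examples
#' xi <- generate_patterns(3, 8, seed = 7)
#' identical(xi, generate_patterns(3, 8, seed = 7))
#' @export
generate_patterns <- function(P, N, seed = NULL) {
  P <- check_count(P, "P")
  N <- check_count(N, "N")
  draw <- function() rand_spin_matrix(P, N)
  m <- if (is.null(seed)) draw() else with_seed(seed, draw())
  as_pattern_set(m, seed = seed)
}

#' Coerce a matrix of spins to a pattern set
#'
#' Validates that every entry is exactly -1 or +1 and attaches the
#' `pattern_set` class and dimension attributes.
#'
#' @param x A numeric matrix with entries in \{-1, +1\}; rows are patterns.
#' @param seed Optional seed to record (absent for user-supplied patterns).
#' @return A `"pattern_set"` matrix.
#' @export
as_pattern_set <- function(x, seed = NULL) {
  if (inherits(x, "pattern_set")) return(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    usage_error("patterns must be a numeric matrix")
  }
  if (!all(x == 1 | x == -1)) {
    usage_error("pattern entries must all be -1 or +1")
  }
  structure(x,
            n_patterns = nrow(x), n_neurons = ncol(x),
            seed = seed,
            class = c("pattern_set", class(x)))
}

#' @export
print.pattern_set <- function(x, max_rows = 10L, ...) {
  P <- nrow(x); N <- ncol(x)
  cat(sprintf("Pattern set: P = %d patterns, N = %d neurons\n", P, N))
  if (!is.null(attr(x, "seed"))) cat("  seed:", attr(x, "seed"), "\n")
  shown <- seq_len(min(P, max_rows))
  for (i in shown) cat(sprintf("  [%d] %s\n", i, format_spins(x[i, ])))
  if (P > max_rows) cat(sprintf("  ... (%d more)\n", P - max_rows))
  invisible(x)
}
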