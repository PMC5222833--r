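#' Hebbian coupling matrix
#'
#' Builds the symmetric coupling matrix
#' \deqn{J_{ij} = \frac{1}{P}\sum_{\mu=1}^{P} \xi_i^\mu \xi_j^\mu}
#' from a pattern set. With `retain_diagonal = TRUE` the self-coupling
#' (autapse) terms are kept, so every diagonal entry is exactly 1; with
#' `FALSE` the diagonal is zeroed afterwards, recovering the classical
#' Hopfield convention. The positive 1/P normalization never affects the sign
#' dynamics but keeps weights in [-1, 1].
#'
#' @param patterns A `pattern_set` or a P x N matrix of +/-1 spins.
#' @param retain_diagonal Keep the diagonal (autapses)? Default `TRUE`.
#' @return An `N x N` matrix of class `"coupling_matrix"` with attributes
#'   `diagonal_retained` and `source_n_patterns`.
#' @examples
#' xi <- generate_patterns(5, 20, seed = 1)
#' J <- hebbian_matrix(xi)
#' all(J == t(J))
#' @export
hebbian_matrix <- function(patterns, retain_diagonal = TRUE) {
  patterns <- as_pattern_set(patterns)
  P <- nrow(patterns)
  J <- crossprod(patterns) / P
  if (!retain_diagonal) diag(J) <- 0
  as_coupling_matrix(J, diagonal_retained = retain_diagonal,
                     source_n_patterns = P)
}

as_coupling_matrix <- function(J, diagonal_retained, source_n_patterns = NULL) {
  structure(J,
            diagonal_retained = diagonal_retained,
            source_n_patterns = source_n_patterns,
            n_neurons = nrow(J),
            class = c("coupling_matrix", class(J)))
}

#' Fit a Hopfield associative memory by Hebbian learning
#'
#' Encodes a training set of +/-1 patterns into a recurrent network via the
#' Hebbian rule and returns the network as a classed object. The network
#' state evolves under the synchronous sign dynamics
#' \deqn{s_i(t+1) = \mathrm{sign}\Big[\sum_j J_{ij} s_j(t)\Big],}
#' with the convention sign(0) = +1. A stored pattern is "retrieved" when one
#' synchronous update returns it unchanged (one-step stability).
#'
#' @param patterns A `pattern_set` or P x N matrix of +/-1 spins (one pattern
#'   per row).
#' @param diagonal Retain the self-coupling (autapse) terms of the Hebbian
#'   matrix? Default `TRUE`; `FALSE` gives the classical zero-diagonal model.
#' @return An object of class `"hopfield"`: a list with components `weights`
#'   (the coupling matrix), `patterns`, `n_neurons`, `n_patterns`, `diagonal`.
#' @seealso [predict.hopfield()], [evolve()], [summary.hopfield()]
#' @examples
#' net <- hopfield(generate_patterns(10, 50, seed = 1))
#' out <- predict(net)                  # one-step outputs for stored patterns
#' mean(out != net$patterns)            # empirical one-step bit-error rate
#' @export
hopfield <- function(patterns, diagonal = TRUE) {
  patterns <- as_pattern_set(patterns)
  J <- hebbian_matrix(patterns, retain_diagonal = diagonal)
  structure(list(weights = J,
                 patterns = patterns,
                 n_neurons = ncol(patterns),
                 n_patterns = nrow(patterns),
                 diagonal = diagonal,
                 call = match.call()),
            class = "hopfield")
}

weights_of <- function(object) {
  if (inherits(object, "hopfield")) return(object$weights)
  if (is.matrix(object) && is.numeric(object)) {
    if (nrow(object) != ncol(object)) {
      usage_error("coupling matrix must be square")
    }
    return(object)
  }
  usage_error("expected a 'hopfield' object or a square numeric matrix")
}

#' One synchronous update of the network state
#'
#' Applies the sign dynamics to all neurons in parallel: each neuron takes the
#' sign of its local field \eqn{\sum_j J_{ij} s_j}, with sign(0) mapped to +1.
#' The input state is not modified.
#'
#' @param object A `hopfield` network or a square coupling matrix.
#' @param s A length-N state vector of +/-1 spins.
#' @return The updated +/-1 state vector.
#' @export
update_step <- function(object, s) {
  J <- weights_of(object)
  if (!is_spin_vector(s)) usage_error("state entries must all be -1 or +1")
  if (length(s) != nrow(J)) {
    usage_error(sprintf("state length %d does not match network size %d",
                        length(s), nrow(J)))
  }
  as.vector(sign0(J %*% s))
}

#' Number of differing spins between two states
#'
#' The distortion measure used throughout: how many bits of one state
#' disagree with another.
#'
#' @param a,b State vectors of equal length.
#' @return Integer count in `[0, N]`.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) {
    usage_error("states must have equal length")
  }
  sum(a != b)
}

#' Iterate the synchronous dynamics to a fixed point or limit cycle
#'
#' Runs the deterministic parallel dynamics from `s0`, recording the Hamming
#' distance to the initial state after every update. Stops at a fixed point
#' (the state reproduces itself), at a limit cycle (the state matches any
#' previously visited state), or after `max_steps` updates. Transients of the
#' finite-size dynamics are short, hence the default cap of `4 * N` steps.
#'
#' @param object A `hopfield` network or square coupling matrix.
#' @param s0 Initial +/-1 state vector.
#' @param max_steps Maximum number of synchronous updates (default `4 * N`).
#' @return A `"hopfield_trajectory"` list: `initial`, `final`, `n_steps`
#'   (updates needed to first reach the final recurrent state), `outcome`
#'   (`"fixed_point"`, `"limit_cycle"` or `"max_steps_reached"`),
#'   `cycle_length` (limit cycles only), and `distortion_trace` (Hamming
#'   distance from `s0`, one entry per update performed).
#' @export
evolve <- function(object, s0, max_steps = NULL) {
  J <- weights_of(object)
  N <- nrow(J)
  if (!is_spin_vector(s0)) usage_error("state entries must all be -1 or +1")
  if (length(s0) != N) usage_error("state length does not match network size")
  if (is.null(max_steps)) max_steps <- 4L * N
  max_steps <- check_count(max_steps, "max_steps")

  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(format_spins(s0), 0L, envir = seen)
  s <- s0
  trace <- integer(0)
  outcome <- "max_steps_reached"
  n_steps <- max_steps
  cycle_length <- NULL

  for (t in seq_len(max_steps)) {
    s_new <- as.vector(sign0(J %*% s))
    trace[t] <- hamming_distance(s_new, s0)
    if (all(s_new == s)) {
      outcome <- "fixed_point"
      n_steps <- t - 1L
      s <- s_new
      break
    }
    key <- format_spins(s_new)
    prev <- seen[[key]]
    if (!is.null(prev)) {
      outcome <- "limit_cycle"
      cycle_length <- t - prev
      n_steps <- t
      s <- s_new
      break
    }
    assign(key, t, envir = seen)
    s <- s_new
  }

  structure(list(initial = s0, final = s, n_steps = n_steps,
                 outcome = outcome, cycle_length = cycle_length,
                 distortion_trace = trace),
            class = "hopfield_trajectory")
}

#' @export
print.hopfield_trajectory <- function(x, ...) {
  cat("Synchronous-dynamics trajectory\n")
  cat("  outcome:", x$outcome,
      if (!is.null(x$cycle_length)) sprintf("(length %d)", x$cycle_length)
      else "", "\n")
  cat("  steps:", x$n_steps, "\n")
  cat("  final distortion from start:",
      hamming_distance(x$final, x$initial), "\n")
  invisible(x)
}

#' @export
print.hopfield <- function(x, ...) {
  cat(sprintf("Hopfield network: N = %d neurons, P = %d stored patterns\n",
              x$n_neurons, x$n_patterns))
  cat("  autapses (diagonal):", if (x$diagonal) "retained" else "zeroed", "\n")
  cat(sprintf("  storage load alpha = P/N = %.4g\n",
              x$n_patterns / x$n_neurons))
  invisible(x)
}

#' Extract the coupling matrix of a fitted network
#' @param object A `hopfield` object.
#' @param ... Unused.
#' @return The `N x N` Hebbian coupling matrix.
#' @export
coef.hopfield <- function(object, ...) {
  object$weights
}

#' One-step (or multi-step) network response to input states
#'
#' Applies `steps` synchronous updates to each row of `newdata`. With the
#' defaults this is exactly the one-step retrieval test: a row is a stable
#' memory iff its output row equals it.
#'
#' @param object A `hopfield` network.
#' @param newdata Matrix of +/-1 states, one per row; defaults to the stored
#'   patterns.
#' @param steps Number of synchronous updates (default 1).
#' @param ... Unused.
#' @return Matrix of the same shape as `newdata` with the evolved states.
#' @export
predict.hopfield <- function(object, newdata = NULL, steps = 1L, ...) {
  if (is.null(newdata)) newdata <- object$patterns
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (!all(newdata == 1 | newdata == -1)) {
    usage_error("state entries must all be -1 or +1")
  }
  if (ncol(newdata) != object$n_neurons) {
    usage_error("state length does not match network size")
  }
  steps <- check_count(steps, "steps")
  S <- unclass(newdata)
  J <- unclass(object$weights)
  for (k in seq_len(steps)) {
    S <- sign0(S %*% J)
  }
  S
}

#' Analytic and empirical retrieval summary of a network
#'
#' Reports the closed-form one-step error probabilities at the network's
#' (N, P) for both diagonal conventions, together with the exact one-step
#' retrieval outcome of this particular realization's stored patterns.
#'
#' @param object A `hopfield` network.
#' @param ... Unused.
#' @return A `"summary.hopfield"` list.
#' @export
summary.hopfield <- function(object, ...) {
  N <- object$n_neurons; P <- object$n_patterns
  out <- predict(object)
  err <- out != object$patterns
  res <- list(
    n_neurons = N, n_patterns = P, diagonal = object$diagonal,
    bit_errors = sum(err),
    unrecovered = sum(rowSums(err) > 0),
    theory = data.frame(
      convention = c("retain_diagonal", "zero_diagonal"),
      p_B = c(p_bit_error(N, P, TRUE), p_bit_error(N, P, FALSE)),
      p_V = c(p_vector_error(N, P, TRUE), p_vector_error(N, P, FALSE)),
      N_V = c(expected_unrecovered(N, P, TRUE),
              expected_unrecovered(N, P, FALSE))))
  class(res) <- "summary.hopfield"
  res
}

#' @export
print.summary.hopfield <- function(x, ...) {
  cat(sprintf("Hopfield network, N = %d, P = %d, autapses %s\n",
              x$n_neurons, x$n_patterns,
              if (x$diagonal) "retained" else "zeroed"))
  cat(sprintf("  this realization: %d/%d stored patterns not one-step stable (%d wrong bits)\n",
              x$unrecovered, x$n_patterns, x$bit_errors))
  cat("  one-step theory at this (N, P):\n")
  print(x$theory, row.names = FALSE, digits = 4)
  invisible(x)
}
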