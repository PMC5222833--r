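# Monte-Carlo experiments, exhaustive oracles and fixed-point censuses.
#
# Retrieval statistics follow the one-step protocol: every stored pattern is
# presented once, exactly one synchronous update is applied, and flipped bits
# / imperfect vectors are counted. Limit cycles are never counted as
# successful retrieval, so one step determines all three quantities.

check_budget <- function(work, budget) {
  if (work > budget) {
    resource_error(sprintf(
      "requested work %.3g exceeds budget %.3g; raise `budget` deliberately",
      work, budget))
  }
}

one_step_errors <- function(X, retain_diagonal) {
  # unnormalized Hebbian field: sign identical to the 1/P-normalized one
  G <- crossprod(X)
  if (!retain_diagonal) diag(G) <- 0
  FF <- X %*% G
  (FF * X < 0) | (FF == 0 & X < 0)
}

#' Monte-Carlo estimate of the one-step retrieval-error probabilities
#'
#' For each of `reps` realizations: draw a fresh random training set, build
#' the Hebbian coupling matrix, present every stored pattern, apply one
#' synchronous update, and count flipped bits and imperfect vectors. Counts
#' are pooled across realizations (identical expectation to averaging
#' per-realization proportions, smaller variance); the per-realization
#' proportions are also recorded. Realization r uses a seed derived
#' deterministically from `(seed, r)`.
#'
#' @param N Network size.
#' @param P Number of stored patterns.
#' @param reps Number of independent random realizations.
#' @param seed Integer experiment seed.
#' @param retain_diagonal Autapse convention.
#' @param budget Resource guard: error if `N * P * reps` exceeds it.
#' @return A `"retrieval_estimate"` list with raw counts, pooled proportions
#'   `p_B_hat`, `p_V_hat`, `N_V_hat = P * p_V_hat`, 95% Wilson interval
#'   half-widths, and a per-realization data frame.
#' @examples
#' estimate_retrieval(50, 50, reps = 50, seed = 1)
#' @export
estimate_retrieval <- function(N, P, reps, seed, retain_diagonal = TRUE,
                               budget = 2e10) {
  N <- check_count(N, "N"); P <- check_count(P, "P")
  reps <- check_count(reps, "reps")
  check_budget(N * P * reps, budget)

  bit_err_by_rep <- integer(reps)
  vec_err_by_rep <- integer(reps)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    X <- rand_spin_matrix(P, N)
    err <- one_step_errors(X, retain_diagonal)
    bit_err_by_rep[r] <- sum(err)
    vec_err_by_rep[r] <- sum(rowSums(err) > 0)
  }

  bit_trials <- N * P * reps
  vector_trials <- P * reps
  bit_errors <- sum(bit_err_by_rep)
  vector_errors <- sum(vec_err_by_rep)
  p_B_hat <- bit_errors / bit_trials
  p_V_hat <- vector_errors / vector_trials

  structure(list(
    N = N, P = P, reps = reps, retain_diagonal = retain_diagonal,
    seed = seed,
    bit_trials = bit_trials, bit_errors = bit_errors,
    vector_trials = vector_trials, vector_errors = vector_errors,
    p_B_hat = p_B_hat, p_V_hat = p_V_hat, N_V_hat = P * p_V_hat,
    ci_halfwidth_bit = wilson_halfwidth(bit_errors, bit_trials),
    ci_halfwidth_vector = wilson_halfwidth(vector_errors, vector_trials),
    per_realization = data.frame(
      rep = seq_len(reps),
      p_B = bit_err_by_rep / (N * P),
      p_V = vec_err_by_rep / P)),
    class = "retrieval_estimate")
}

#' @export
print.retrieval_estimate <- function(x, ...) {
  cat(sprintf("One-step retrieval estimate: N = %d, P = %d, %d realizations, autapses %s\n",
              x$N, x$P, x$reps,
              if (x$retain_diagonal) "retained" else "zeroed"))
  cat(sprintf("  p_B_hat = %.4g (+/- %.2g)   p_V_hat = %.4g (+/- %.2g)   N_V_hat = %.4g\n",
              x$p_B_hat, x$ci_halfwidth_bit,
              x$p_V_hat, x$ci_halfwidth_vector, x$N_V_hat))
  invisible(x)
}

#' Monte-Carlo estimate of the spurious-state rejection probabilities
#'
#' Per realization, draws `probes` random vectors, redrawing any that exactly
#' matches a stored pattern (probes must lie outside the training set), then
#' applies one synchronous update. A probe whose output differs from itself
#' counts as a correct rejection (toward \eqn{\bar p_V}); each differing bit
#' counts toward \eqn{\bar p_B}. Autapses are retained, the setting in which
#' spurious-state discrimination is at issue.
#'
#' @inheritParams estimate_retrieval
#' @param probes Probe vectors per realization (default `P`, mirroring the
#'   stored-pattern sample size).
#' @return A `"spurious_estimate"` list with pooled counts, `pbar_B_hat`,
#'   `pbar_V_hat` and Wilson interval half-widths.
#' @export
estimate_spurious <- function(N, P, reps, probes = P, seed, budget = 2e10) {
  N <- check_count(N, "N"); P <- check_count(P, "P")
  reps <- check_count(reps, "reps"); probes <- check_count(probes, "probes")
  check_budget(N * (P + probes) * reps, budget)

  bit_count <- 0; vec_count <- 0
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    X <- rand_spin_matrix(P, N)
    if (N <= 25) {
      n_distinct <- nrow(unique(X))
      if (n_distinct >= 2^N) {
        usage_error(sprintf(
          "no state outside the training set exists at N = %d", N))
      }
    }
    Z <- rand_spin_matrix(probes, N)
    for (k in 1:1000) {
      hits <- rowSums(tcrossprod(Z, X) == N) > 0
      if (!any(hits)) break
      Z[hits, ] <- rand_spin_matrix(sum(hits), N)
      if (k == 1000) {
        resource_error("could not draw probes outside the training set")
      }
    }
    G <- crossprod(X)
    FF <- Z %*% G
    diffbit <- (FF * Z < 0) | (FF == 0 & Z < 0)
    bit_count <- bit_count + sum(diffbit)
    vec_count <- vec_count + sum(rowSums(diffbit) > 0)
  }

  bit_trials <- N * probes * reps
  vector_trials <- probes * reps
  structure(list(
    N = N, P = P, reps = reps, probes = probes, seed = seed,
    bit_trials = bit_trials, bit_count = bit_count,
    vector_trials = vector_trials, vector_count = vec_count,
    pbar_B_hat = bit_count / bit_trials,
    pbar_V_hat = vec_count / vector_trials,
    ci_halfwidth_bit = wilson_halfwidth(bit_count, bit_trials),
    ci_halfwidth_vector = wilson_halfwidth(vec_count, vector_trials)),
    class = "spurious_estimate")
}

#' @export
print.spurious_estimate <- function(x, ...) {
  cat(sprintf("Spurious-probe estimate: N = %d, P = %d, %d probes x %d realizations\n",
              x$N, x$P, x$probes, x$reps))
  cat(sprintf("  pbar_B_hat = %.4g (+/- %.2g)   pbar_V_hat = %.4g (+/- %.2g)\n",
              x$pbar_B_hat, x$ci_halfwidth_bit,
              x$pbar_V_hat, x$ci_halfwidth_vector))
  invisible(x)
}

#' Monte-Carlo sweep over a grid of network sizes and storage levels
#'
#' Runs [estimate_retrieval()] on the product grid `N_list x P_list`, with a
#' deterministic per-cell seed derived from `(seed, N, P, convention)`, and
#' attaches the closed-form `p_B`, `p_V`, `N_V` for both diagonal
#' conventions.
#'
#' @param N_list,P_list Integer vectors of network sizes and storage levels.
#' @inheritParams estimate_retrieval
#' @return A data frame of class `"capacity_grid"`, one row per (N, P) cell,
#'   with empirical estimates, Wilson half-widths, and analytic values for
#'   the simulated convention (`p_B_theory`, ...) and for both conventions
#'   (`*_theory_retain`, `*_theory_zero`).
#' @export
sweep_capacity <- function(N_list, P_list, reps, seed, retain_diagonal = TRUE,
                           budget = 2e10) {
  if (length(N_list) < 1 || length(P_list) < 1) {
    usage_error("N_list and P_list must be non-empty")
  }
  rows <- vector("list", length(N_list) * length(P_list))
  i <- 0
  for (N in N_list) for (P in P_list) {
    i <- i + 1
    est <- tryCatch(
      estimate_retrieval(N, P, reps,
                         seed = derive_seed(seed, N, P, retain_diagonal),
                         retain_diagonal = retain_diagonal, budget = budget),
      hopcapacity_resource_error = function(e) {
        resource_error(sprintf("cell (N = %d, P = %d): %s", N, P,
                               conditionMessage(e)))
      })
    suppressMessages(rows[[i]] <- data.frame(
      N = N, P = P, alpha = P / N, reps = reps, seed = seed,
      p_B_hat = est$p_B_hat, ci_bit = est$ci_halfwidth_bit,
      p_V_hat = est$p_V_hat, ci_vec = est$ci_halfwidth_vector,
      N_V_hat = est$N_V_hat,
      p_B_theory = p_bit_error(N, P, retain_diagonal),
      p_V_theory = p_vector_error(N, P, retain_diagonal),
      N_V_theory = expected_unrecovered(N, P, retain_diagonal),
      retain_diagonal = retain_diagonal,
      p_B_theory_retain = p_bit_error(N, P, TRUE),
      p_V_theory_retain = p_vector_error(N, P, TRUE),
      N_V_theory_retain = expected_unrecovered(N, P, TRUE),
      p_B_theory_zero = p_bit_error(N, P, FALSE),
      p_V_theory_zero = p_vector_error(N, P, FALSE),
      N_V_theory_zero = expected_unrecovered(N, P, FALSE)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("capacity_grid", "data.frame")
  out
}

#' Plot a capacity sweep against theory
#'
#' Log-log plot of an empirical quantity versus P, one curve per network
#' size, with the closed-form prediction overlaid as lines.
#'
#' @param x A `"capacity_grid"` from [sweep_capacity()].
#' @param quantity `"p_B"`, `"p_V"` or `"N_V"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.capacity_grid <- function(x, quantity = c("p_B", "p_V", "N_V"), ...) {
  quantity <- match.arg(quantity)
  hat <- paste0(quantity, "_hat")
  th <- paste0(quantity, "_theory")
  Ns <- sort(unique(x$N))
  cols <- grDevices::hcl.colors(max(length(Ns), 2), "Dark 3")
  keep <- x[[hat]] > 0 | x[[th]] > 0
  graphics::plot(NA, xlim = range(x$P), ylim = range(c(x[[hat]][keep],
                                                       x[[th]][keep])),
                 log = "xy", xlab = "P (stored patterns)", ylab = quantity,
                 ...)
  for (i in seq_along(Ns)) {
    d <- x[x$N == Ns[i], ]
    d <- d[order(d$P), ]
    graphics::points(d$P, d[[hat]], col = cols[i], pch = 16)
    graphics::lines(d$P, d[[th]], col = cols[i])
  }
  graphics::legend("topright", legend = paste("N =", Ns),
                   col = cols[seq_along(Ns)], lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Exact one-step bit-error probability by exhaustive enumeration
#'
#' Enumerates every one of the \eqn{2^{NP}} possible pattern matrices,
#' applies one synchronous update to each stored pattern, and averages the
#' bit-error fraction with equal weights. This is the brute-force oracle for
#' the Monte-Carlo estimator and for the Gaussian theory at tiny sizes; ties
#' (zero local field) follow the package-wide sign(0) = +1 convention.
#'
#' @inheritParams estimate_retrieval
#' @return The exact probability (a rational number with denominator
#'   dividing \eqn{2^{NP} N P}), with attributes `total_bit_errors` and
#'   `n_configurations`.
#' @export
exhaustive_bit_error <- function(N, P, retain_diagonal = TRUE) {
  N <- check_count(N, "N"); P <- check_count(P, "P")
  if (N * P > 20) {
    resource_error("exhaustive enumeration requires N * P <= 20")
  }
  nb <- N * P
  n_cfg <- 2^nb
  pw <- 2^(0:(nb - 1))
  total <- 0
  for (k in 0:(n_cfg - 1)) {
    X <- matrix(2 * ((k %/% pw) %% 2) - 1, nrow = P, ncol = N)
    total <- total + sum(one_step_errors(X, retain_diagonal))
  }
  structure(total / (n_cfg * N * P),
            total_bit_errors = total, n_configurations = n_cfg)
}

# N x m matrix of the spin states with the given 0-based indices.
decode_states <- function(N, idx) {
  S <- matrix(0, nrow = N, ncol = length(idx))
  for (b in seq_len(N)) {
    S[b, ] <- 2 * ((idx %/% 2^(b - 1)) %% 2) - 1
  }
  S
}

#' Exhaustive census of the fixed points of a network
#'
#' Tests every one of the \eqn{2^N} spin states for invariance under one
#' synchronous update (in chunks, so memory stays bounded). Under the
#' sign(0) = +1 convention the all-zero coupling matrix has exactly one
#' fixed point, the all-plus state.
#'
#' @param object A `hopfield` network or square coupling matrix with
#'   `N <= 22`.
#' @param keep_states Also return the fixed states themselves (as rows)?
#' @return A `"fixed_point_census"` list: `n_neurons`, `count`, and (when
#'   `keep_states`) the matrix `fixed_states`.
#' @examples
#' net <- hopfield(generate_patterns(1, 5, seed = 3))
#' count_fixed_points(net)$count    # 2: the pattern and its mirror
#' @export
count_fixed_points <- function(object, keep_states = TRUE) {
  J <- weights_of(object)
  N <- nrow(J)
  if (N > 22) resource_error("exhaustive census requires N <= 22")
  total <- 0
  states <- list()
  chunk <- 2^min(N, 14)
  for (start in seq(0, 2^N - 1, by = chunk)) {
    S <- decode_states(N, start:(start + chunk - 1))
    FF <- J %*% S
    ok <- colSums((FF * S > 0) | (FF == 0 & S > 0)) == N
    total <- total + sum(ok)
    if (keep_states && any(ok)) states[[length(states) + 1]] <- t(S[, ok,
                                                                   drop = FALSE])
  }
  out <- list(n_neurons = N, count = total)
  if (keep_states) {
    out$fixed_states <- if (length(states)) do.call(rbind, states)
                        else matrix(0, 0, N)
  }
  structure(out, class = "fixed_point_census")
}

#' @export
print.fixed_point_census <- function(x, ...) {
  cat(sprintf("Fixed-point census: N = %d, %d of %.0f states are fixed points\n",
              x$n_neurons, x$count, 2^x$n_neurons))
  invisible(x)
}

#' Exponential growth rate of the fixed-point count of random networks
#'
#' Random fully connected symmetric networks hold a number of fixed points
#' growing as \eqn{e^{\gamma N}} with \eqn{\gamma \approx 0.2}. For each N in
#' `N_min:N_max` this draws `reps` coupling matrices with independent
#' standard-normal symmetric off-diagonal weights and zero diagonal (the
#' spin-glass convention of that literature), counts fixed points by
#' exhaustive enumeration, and fits mean ln(count) against N by least
#' squares.
#'
#' @param N_min,N_max Network-size range (`8 <= N_min < N_max <= 20`).
#' @param reps Matrices per size.
#' @param seed Integer experiment seed.
#' @param matrix_fn Optional generator `function(N)` returning a coupling
#'   matrix, replacing the Gaussian ensemble (used e.g. for closed-form
#'   degenerate checks).
#' @return A `"gamma_estimate"` list: `gamma_hat` (the slope, nats per
#'   neuron), `se`, the per-size table `by_N` (`N`, `mean_log_count`), and
#'   the fitted `lm` object.
#' @export
estimate_gamma <- function(N_min = 10, N_max = 16, reps = 100, seed = 1,
                           matrix_fn = NULL) {
  N_min <- check_count(N_min, "N_min", min = 8L)
  N_max <- check_count(N_max, "N_max")
  if (N_min >= N_max || N_max > 20) {
    usage_error("need 8 <= N_min < N_max <= 20")
  }
  reps <- check_count(reps, "reps")
  check_budget(2^N_max * reps, 2e9)
  if (is.null(matrix_fn)) matrix_fn <- random_symmetric_matrix

  Ns <- N_min:N_max
  mean_log <- numeric(length(Ns))
  counts <- vector("list", length(Ns))
  for (i in seq_along(Ns)) {
    N <- Ns[i]
    cts <- numeric(reps)
    for (r in seq_len(reps)) {
      set.seed(derive_seed(seed, N, r))
      cts[r] <- count_fixed_points(matrix_fn(N), keep_states = FALSE)$count
    }
    if (any(cts == 0)) {
      warning("replicates with zero fixed points dropped from the log mean")
      cts <- cts[cts > 0]
    }
    counts[[i]] <- cts
    mean_log[i] <- mean(log(cts))
  }

  fit <- stats::lm(mean_log ~ Ns)
  sm <- summary(fit)$coefficients
  structure(list(gamma_hat = unname(stats::coef(fit)[2]),
                 se = unname(sm["Ns", "Std. Error"]),
                 by_N = data.frame(N = Ns, mean_log_count = mean_log),
                 counts = counts, reps = reps, seed = seed, fit = fit),
            class = "gamma_estimate")
}

# Symmetric coupling matrix with iid N(0,1) strictly-upper-triangle weights
# mirrored below and zero diagonal.
random_symmetric_matrix <- function(N) {
  W <- matrix(0, N, N)
  up <- upper.tri(W)
  W[up] <- stats::rnorm(sum(up))
  W + t(W)
}

#' @export
print.gamma_estimate <- function(x, ...) {
  cat(sprintf("Fixed-point growth rate: gamma_hat = %.4f (SE %.4f), N = %d..%d, %d matrices each\n",
              x$gamma_hat, x$se, min(x$by_N$N), max(x$by_N$N), x$reps))
  invisible(x)
}
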