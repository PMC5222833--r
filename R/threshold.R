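# Perfect-recovery storage threshold: the P at which the expected number of
# unrecovered patterns crosses N_V = 1.

#' Lambert W function, real branch -1
#'
#' Solves \eqn{w e^w = x} for the second real branch \eqn{w \le -1}, defined
#' on \eqn{x \in [-1/e, 0)}. Halley iteration started from the logarithmic
#' expansion \eqn{W_{-1}(-y) \approx \ln y - \ln(-\ln y)} (a branch-point
#' series is used instead for x near \eqn{-1/e}, where the log expansion is
#' poor and plain iteration risks jumping to the principal branch). Converges
#' to a relative back-substitution residual below 1e-12.
#'
#' @param x Numeric vector in `[-1/e, 0)`.
#' @return `w <= -1` with `w * exp(w) == x` to high relative accuracy.
#' @examples
#' lambert_w_m1(-0.1)                       # ~ -3.577152
#' w <- lambert_w_m1(-1e-8); w * exp(w)     # back-substitutes to -1e-8
#' @export
lambert_w_m1 <- function(x) {
  if (any(!is.finite(x)) || any(x < -exp(-1) * (1 + 1e-12)) || any(x >= 0)) {
    usage_error("x must lie in [-1/e, 0)")
  }
  vapply(x, lambert_w_m1_scalar, numeric(1))
}

lambert_w_m1_scalar <- function(x) {
  if (abs(x + exp(-1)) < 1e-16) return(-1)
  # initial guess
  if (x > -0.27) {
    # branch-point series in p = sqrt(2(1 + e x)); W_-1 = -1 - p - p^2/3 - ...
    p <- sqrt(2 * (1 + exp(1) * x))
    w <- -1 - p - p^2 / 3 - 11 * p^3 / 72
  } else {
    ly <- log(-x)
    w <- ly - log(-ly)
  }
  for (k in 1:50) {
    ew <- exp(w)
    f <- w * ew - x
    if (abs(f) <= 1e-13 * abs(x)) break
    # Halley step
    d <- ew * (w + 1) - (w + 2) * f / (2 * (w + 1))
    w_new <- w - f / d
    if (w_new > -1) w_new <- -1 - 0.5 * (abs(w) - 1)  # stay on the branch
    if (abs(w_new - w) <= 1e-15 * abs(w)) { w <- w_new; break }
    w <- w_new
  }
  w
}

#' Perfect-recovery storage threshold P(N)
#'
#' For an autapse-retaining network of N neurons, the storage level P above
#' which the expected number of unrecovered patterns drops below one.
#' Squaring the large-\eqn{\alpha} condition \eqn{N_V = 1} gives
#' \eqn{\alpha e^{-\alpha} = 2\pi/N^4}, inverted exactly by the Lambert
#' function,
#' \deqn{P(N) = -N\, W_{-1}\!\left(-2\pi/N^4\right),}
#' and approximately, via the small-argument expansion of \eqn{W_{-1}}, by
#' \deqn{P(N) = N\left[\ln\frac{N^4}{2\pi} +
#'   \ln\ln\frac{N^4}{2\pi}\right].}
#' All three routes are computed: a bracketed root search for the real-valued
#' P solving \eqn{N_V(N, P) = 1} exactly (relative tolerance 1e-9), the
#' Lambert-W inversion, and the logarithmic expansion. Perfect recovery also
#' occurs on a second, classical branch at small load; the numeric solver
#' exposes it via `branch = "low_alpha"` (the Lambert form is derived for the
#' high-load branch only and is `NA` there).
#'
#' @param N Network size (`>= 5`, so the Lambert argument is inside the
#'   branch domain).
#' @param branch `"high_alpha"` (root with `P > N`) or `"low_alpha"`
#'   (`P < N`).
#' @return A `"recovery_threshold"` list: `n_neurons`, `branch`,
#'   `p_numeric_root`, `p_lambert`, `p_log_expansion`, and `p_integer`
#'   (ceiling of the numeric root, the first guaranteed integer level on the
#'   high branch).
#' @examples
#' perfect_recovery_threshold(1000)
#' @export
perfect_recovery_threshold <- function(N, branch = c("high_alpha",
                                                     "low_alpha")) {
  branch <- match.arg(branch)
  N <- check_count(N, "N", min = 5L)

  g <- function(P) expected_unrecovered(N, P) - 1

  if (branch == "high_alpha") {
    if (g(N) <= 0) {
      stop(sprintf("no perfect-recovery root with P > N: N_V never exceeds 1 at N = %d",
                   N), call. = FALSE)
    }
    hi <- 2 * N
    for (k in 1:60) {
      if (g(hi) < 0) break
      hi <- hi * 2
    }
    if (g(hi) >= 0) stop("failed to bracket the high-load root", call. = FALSE)
    root <- stats::uniroot(g, lower = N, upper = hi,
                           tol = 1e-9 * hi)$root
    p_lam <- -N * lambert_w_m1(-2 * pi / N^4)
    l <- log(N^4 / (2 * pi))
    p_log <- N * (l + log(l))
  } else {
    if (g(N) <= 0) {
      stop(sprintf("no perfect-recovery root with P < N at N = %d", N),
           call. = FALSE)
    }
    root <- stats::uniroot(g, lower = 1 + 1e-9, upper = N,
                           tol = 1e-9 * N)$root
    p_lam <- NA_real_
    p_log <- NA_real_
  }

  structure(list(n_neurons = N, branch = branch,
                 p_numeric_root = root,
                 p_lambert = p_lam,
                 p_log_expansion = p_log,
                 p_integer = ceiling(root)),
            class = "recovery_threshold")
}

#' @export
print.recovery_threshold <- function(x, ...) {
  cat(sprintf("Perfect-recovery threshold, N = %d (%s branch)\n",
              x$n_neurons, x$branch))
  cat(sprintf("  numeric root of N_V = 1 : %.6g  (first integer level %d)\n",
              x$p_numeric_root, x$p_integer))
  if (!is.na(x$p_lambert)) {
    cat(sprintf("  Lambert-W inversion     : %.6g\n", x$p_lambert))
    cat(sprintf("  log expansion           : %.6g\n", x$p_log_expansion))
  }
  invisible(x)
}
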