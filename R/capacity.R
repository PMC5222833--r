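# Closed-form one-step retrieval-error theory.
#
# Signal-to-noise decomposition of the local field of a stored pattern:
# A_i^mu = (N + P - 1) xi_i^mu + T_i^mu, where T pools the (N-1)(P-1)
# crossed terms, treated as Gaussian with variance (N-1)(P-1). With the
# diagonal zeroed the coherent weight drops to N - 1. All tail probabilities
# go through pnorm(..., lower.tail = FALSE), the stable complementary-error-
# function route: 0.5*erfc(x) == pnorm(x*sqrt(2), lower.tail = FALSE).

coherent_term <- function(N, P, retain_diagonal) {
  if (retain_diagonal) N + P - 1 else N - 1
}

#' Probability that one bit of a stored pattern flips in one update
#'
#' The single-bit retrieval-error probability
#' \deqn{p_B = \tfrac12\,\mathrm{erfc}\!\left(\frac{N+P-1}{\sqrt{2(N-1)(P-1)}}\right)}
#' for the autapse-retaining network; with the diagonal zeroed the numerator
#' becomes \eqn{N - 1}. Symmetric in N and P in the retained case, with
#' maximum \eqn{(1-\mathrm{erf}\sqrt2)/2 \approx 0.02275} approached at
#' \eqn{P = N} for large networks.
#'
#' When \eqn{(N-1)(P-1) = 0} there is no noise term at all and the exact
#' answer is used: 0 whenever the coherent term is positive.
#'
#' @param N Number of neurons (vectorized).
#' @param P Number of stored patterns (vectorized).
#' @param retain_diagonal Autapse convention (default `TRUE`).
#' @return Bit-error probability in `[0, 0.5]`.
#' @examples
#' p_bit_error(50, 50)          # ~ 0.0217
#' p_bit_error(1e6, 1e6)        # ~ 0.02275, the large-network maximum
#' @export
p_bit_error <- function(N, P, retain_diagonal = TRUE) {
  if (any(N < 1 | P < 1)) usage_error("N and P must be >= 1")
  num <- coherent_term(N, P, retain_diagonal)
  v <- (N - 1) * (P - 1)
  out <- ifelse(v > 0,
                stats::pnorm(num / sqrt(pmax(v, 1)), lower.tail = FALSE),
                ifelse(num > 0, 0, 0.5))
  if (any(v == 0)) {
    message("degenerate case (N-1)(P-1) = 0: exact no-noise probability used")
  }
  out
}

#' Probability that a stored pattern is not one-step stable
#'
#' Vector-level error probability \eqn{p_V = 1 - (1 - p_B)^N}: at least one
#' of the N bits flips. Evaluated via `expm1`/`log1p` so tiny `p_B` does not
#' lose precision.
#'
#' @inheritParams p_bit_error
#' @return Probability in `[0, 1]`.
#' @export
p_vector_error <- function(N, P, retain_diagonal = TRUE) {
  pB <- p_bit_error(N, P, retain_diagonal)
  -expm1(N * log1p(-pB))
}

#' Expected number of unrecovered stored patterns
#'
#' \eqn{N_V = P \, p_V}, the expected count of training patterns that are not
#' fixed points under one synchronous update. Perfect recovery is the regime
#' \eqn{N_V < 1}.
#'
#' @inheritParams p_bit_error
#' @return Non-negative expected count, at most `P`.
#' @export
expected_unrecovered <- function(N, P, retain_diagonal = TRUE) {
  P * p_vector_error(N, P, retain_diagonal)
}

#' Large-network asymptotic forms of the retrieval-error quantities
#'
#' Closed-form asymptotics obtained from the tail expansion
#' \eqn{\mathrm{erf}(x) \approx 1 - e^{-x^2}/(x\sqrt\pi)} and
#' \eqn{(1-p_B)^N \approx 1 - N p_B} (autapse-retaining convention):
#' \describe{
#'   \item{`p_V`}{\eqn{N^{3/2} P^{1/2} e^{-(N+P)^2/(2NP)} / (\sqrt{2\pi}(N+P))}}
#'   \item{`N_V`}{\eqn{N^{3/2} P^{3/2} e^{-(N+P)^2/(2NP)} / (\sqrt{2\pi}(N+P))}
#'     — symmetric under exchanging N and P, unlike the exact form}
#'   \item{`p_B_alpha`}{\eqn{\tfrac12[1 - \mathrm{erf}((1+\alpha)/\sqrt{2\alpha})]}
#'     with \eqn{\alpha = P/N}}
#'   \item{`N_V_alpha`}{\eqn{NP\sqrt\alpha\, e^{-(1+\alpha)^2/(2\alpha)} /
#'     (\sqrt{2\pi}(1+\alpha))}, identical to `N_V` when \eqn{P = \alpha N}}
#' }
#' These are accurate near the perfect-recovery contour \eqn{N_V \approx 1}
#' and degrade deep in the tails at small N (the dropped `-1` terms enter the
#' exponent).
#'
#' @inheritParams p_bit_error
#' @param quantity One of `"p_V"`, `"N_V"`, `"p_B_alpha"`, `"N_V_alpha"`.
#' @return The requested asymptotic value.
#' @export
capacity_asymptotic <- function(N, P,
                                quantity = c("p_V", "N_V", "p_B_alpha",
                                             "N_V_alpha")) {
  quantity <- match.arg(quantity)
  if (any(N < 2 | P < 2)) usage_error("N and P must be >= 2")
  alpha <- P / N
  switch(quantity,
    p_V = exp(1.5 * log(N) + 0.5 * log(P) - (N + P)^2 / (2 * N * P) -
                0.5 * log(2 * pi) - log(N + P)),
    N_V = exp(1.5 * log(N) + 1.5 * log(P) - (N + P)^2 / (2 * N * P) -
                0.5 * log(2 * pi) - log(N + P)),
    p_B_alpha = stats::pnorm((1 + alpha) / sqrt(alpha), lower.tail = FALSE),
    N_V_alpha = exp(log(N) + log(P) + 0.5 * log(alpha) -
                      (1 + alpha)^2 / (2 * alpha) - 0.5 * log(2 * pi) -
                      log1p(alpha)))
}

#' Probability of correctly rejecting a non-training probe
#'
#' For a random probe vector that does not belong to the training set
#' (autapse-retaining network), the probability that a given bit changes
#' under one update is
#' \deqn{\bar p_B = \tfrac12\,\mathrm{erfc}\!\left(\frac{P}{\sqrt{2(N-1)(P-1)}}\right),}
#' and \eqn{\bar p_V = 1 - (1-\bar p_B)^N} is the probability the probe is
#' correctly not retrieved (the output differs from the input somewhere).
#' `"vector_asymptotic"` evaluates the large-N form
#' \eqn{\bar p_V \approx N^{3/2} P^{-1/2} e^{-P/(2N)} / \sqrt{2\pi}}, valid
#' for \eqn{N \ll P \ll N^2}.
#'
#' @inheritParams p_bit_error
#' @param level One of `"bit"`, `"vector"`, `"vector_asymptotic"`.
#' @return Probability (bit or vector level).
#' @export
spurious_error_prob <- function(N, P,
                                level = c("bit", "vector",
                                          "vector_asymptotic")) {
  level <- match.arg(level)
  if (any(N < 2 | P < 2)) usage_error("N and P must be >= 2")
  pbB <- stats::pnorm(P / sqrt((N - 1) * (P - 1)), lower.tail = FALSE)
  switch(level,
    bit = pbB,
    vector = -expm1(N * log1p(-pbB)),
    vector_asymptotic = exp(1.5 * log(N) - 0.5 * log(P) - P / (2 * N) -
                              0.5 * log(2 * pi)))
}

#' Discrimination ratio between spurious and memory states
#'
#' The ratio \eqn{\rho = \bar p_V / p_V} between the probability of correctly
#' rejecting a non-training probe and the probability of wrongly rejecting a
#' stored memory. In terms of the storage load \eqn{\alpha = P/N},
#' \deqn{\rho = \frac{1+\alpha}{\alpha}\, e^{1 + 1/(2\alpha)},}
#' which decreases toward the finite limit \eqn{e} as \eqn{\alpha \to \infty}:
#' even when the coupling matrix is dominated by its diagonal, stored
#' memories are retrieved about 2.7 times more reliably than random probes.
#'
#' @param alpha Storage load `P/N` (for `form = "alpha"`).
#' @param form `"alpha"` (ratio at given load), `"exact_np"` (from `N` and
#'   `P` directly), or `"limit"` (the constant `e`).
#' @param N,P Used by `form = "exact_np"`.
#' @return The ratio \eqn{\rho > e}.
#' @examples
#' discrimination_ratio(1)            # 2 e^1.5 ~ 8.963
#' discrimination_ratio(form = "limit")
#' @export
discrimination_ratio <- function(alpha = NULL,
                                 form = c("alpha", "exact_np", "limit"),
                                 N = NULL, P = NULL) {
  form <- match.arg(form)
  if (form == "limit") return(exp(1))
  if (form == "exact_np") {
    if (is.null(N) || is.null(P)) {
      usage_error("form = \"exact_np\" requires N and P")
    }
    if (any(N <= 0 | P <= 0)) usage_error("N and P must be positive")
    return(((N + P) / P) * exp((N + P)^2 / (2 * N * P) - P / (2 * N)))
  }
  if (is.null(alpha) || any(alpha <= 0)) {
    usage_error("alpha must be positive")
  }
  ((1 + alpha) / alpha) * exp(1 + 1 / (2 * alpha))
}
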