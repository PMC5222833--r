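# Frozen values below were computed from independent oracles:
# pracma::erfc for moderate arguments, base pnorm far-tail composition
# checked by high-precision back-substitution.

test_that("single-bit error probability matches the erfc oracle", {
  # oracle: pracma::erfc(99 / (49 * sqrt(2))) / 2
  expect_equal(p_bit_error(50, 50), 0.02167053369, tolerance = 1e-9)
  # oracle grid where erfc does not underflow
  for (N in c(10, 40, 120)) for (P in c(5, 60, 300)) {
    x <- (N + P - 1) / sqrt(2 * (N - 1) * (P - 1))
    if (x < 6) {
      expect_equal(p_bit_error(N, P), pracma::erfc(x) / 2, tolerance = 1e-12)
    }
    x0 <- (N - 1) / sqrt(2 * (N - 1) * (P - 1))
    expect_equal(p_bit_error(N, P, retain_diagonal = FALSE),
                 pracma::erfc(x0) / 2, tolerance = 1e-12)
  }
})

test_that("bit-error formula is symmetric, bounded and correct in limits", {
  expect_identical(p_bit_error(50, 200), p_bit_error(200, 50))
  # large-network maximum at P = N
  expect_equal(signif(p_bit_error(1e6, 1e6), 4), 0.02275)
  # a single stored pattern is always a fixed point with autapses
  expect_equal(suppressMessages(p_bit_error(37, 1)), 0)
  # zero-diagonal error saturates at 1/2 as P grows
  expect_gt(p_bit_error(50, 1e9, retain_diagonal = FALSE), 0.499)
  expect_lt(p_bit_error(50, 1e9, retain_diagonal = FALSE), 0.5)
  # retained-diagonal error vanishes as P grows
  expect_lt(p_bit_error(50, 1e9, retain_diagonal = TRUE), 1e-100)
  expect_message(p_bit_error(10, 1), "degenerate")
  expect_error(p_bit_error(0, 5), ">= 1")
})

test_that("vector-level quantities compose exactly from the bit level", {
  for (N in c(1, 17, 50, 230)) for (P in c(2, 50, 900)) {
    pB <- p_bit_error(N, P)
    pV <- p_vector_error(N, P)
    if (pB > 1e-8) {
      # naive form is representable here
      expect_equal(pV, 1 - (1 - pB)^N, tolerance = 1e-6)
    } else {
      # below double resolution of (1-pB)^N: check the Taylor bound
      # |p_V - N pB| <= (N pB)^2 instead
      expect_lt(abs(pV - N * pB), max((N * pB)^2, 1e-300))
    }
    expect_equal(expected_unrecovered(N, P), P * pV)
    expect_lte(expected_unrecovered(N, P), P)
  }
  expect_equal(p_vector_error(1, 70), p_bit_error(1, 70))
  expect_equal(suppressMessages(p_vector_error(12, 1)), 0)
  # frozen composition of the erfc oracle at N = P = 50
  expect_equal(p_vector_error(50, 50), 0.6656073584, tolerance = 1e-8)
  expect_equal(expected_unrecovered(50, 50), 33.28036792, tolerance = 1e-6)
})

test_that("asymptotic forms are symmetric, mutually consistent, and accurate near the recovery contour", {
  # exchange symmetry recovered by the approximation
  expect_equal(capacity_asymptotic(80, 400, "N_V"),
               capacity_asymptotic(400, 80, "N_V"))
  # alpha parameterization is the same formula when P = alpha N
  expect_equal(capacity_asymptotic(100, 100, "N_V"),
               capacity_asymptotic(100, 100, "N_V_alpha"), tolerance = 1e-12)
  expect_equal(capacity_asymptotic(60, 480, "N_V"),
               capacity_asymptotic(60, 480, "N_V_alpha"), tolerance = 1e-12)
  # alpha <-> 1/alpha mirror: swap the roles of N and P
  expect_equal(capacity_asymptotic(100, 400, "N_V_alpha"),
               capacity_asymptotic(400, 100, "N_V_alpha"), tolerance = 1e-12)
  # p_B in alpha form approaches the exact value for large N at fixed alpha
  expect_equal(capacity_asymptotic(5000, 5000, "p_B_alpha"),
               p_bit_error(5000, 5000), tolerance = 1e-3)
  # near the perfect-recovery contour the N_V approximation is accurate
  rel <- function(N, P) {
    abs(capacity_asymptotic(N, P, "N_V") - expected_unrecovered(N, P)) /
      expected_unrecovered(N, P)
  }
  expect_lt(rel(100, 2330), 0.20)
  expect_lt(rel(1000, 29166), 0.05)
  expect_equal(capacity_asymptotic(100, 100, "p_V") * 100,
               capacity_asymptotic(100, 100, "N_V"), tolerance = 1e-12)
  expect_error(capacity_asymptotic(50, 50, "nope"))
})

test_that("spurious-state rejection probabilities follow the closed forms", {
  # oracle: pracma::erfc(50 / (49 * sqrt(2))) / 2
  expect_equal(spurious_error_prob(50, 50, "bit"), 0.153767462,
               tolerance = 1e-8)
  for (N in c(20, 50, 200)) for (P in c(10, 100, 1500)) {
    pbB <- spurious_error_prob(N, P, "bit")
    pbV <- spurious_error_prob(N, P, "vector")
    if (pbB > 1e-8) {
      expect_equal(pbV, 1 - (1 - pbB)^N, tolerance = 1e-6)
    } else {
      expect_lt(abs(pbV - N * pbB), max((N * pbB)^2, 1e-300))
    }
  }
  # large-N asymptotic valid in the N << P << N^2 window
  rel <- function(N, P) {
    v <- spurious_error_prob(N, P, "vector")
    abs(spurious_error_prob(N, P, "vector_asymptotic") - v) / v
  }
  expect_lt(rel(500, 10000), 0.10)
  expect_lt(rel(1000, 20000), 0.10)
})

test_that("discrimination ratio decreases to the limit e", {
  expect_equal(discrimination_ratio(form = "limit"), exp(1))
  expect_equal(discrimination_ratio(1), 2 * exp(1.5), tolerance = 1e-12)
  expect_equal(round(discrimination_ratio(1e8), 1), 2.7)
  expect_equal(discrimination_ratio(form = "exact_np", N = 50, P = 500),
               discrimination_ratio(10), tolerance = 1e-12)
  a <- exp(seq(log(0.3), log(1e4), length.out = 400))
  rho <- discrimination_ratio(a)
  expect_true(all(diff(rho) < 0))
  expect_true(all(rho > exp(1)))
  expect_error(discrimination_ratio(-1), "positive")
  expect_error(discrimination_ratio(form = "exact_np"), "requires")
})
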