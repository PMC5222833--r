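test_that("below the noise bound the one-step simulation is error-free", {
  # at N = 3, P = 2 the coherent term (4) exceeds the maximum noise (2)
  est <- estimate_retrieval(3, 2, reps = 100, seed = 5)
  expect_equal(est$bit_errors, 0)
  expect_equal(est$vector_errors, 0)
  expect_equal(est$N_V_hat, 0)
})

test_that("retrieval estimates are reproducible and internally consistent", {
  a <- estimate_retrieval(20, 10, reps = 50, seed = 9)
  b <- estimate_retrieval(20, 10, reps = 50, seed = 9)
  expect_identical(a$bit_errors, b$bit_errors)
  expect_identical(a$per_realization, b$per_realization)
  expect_equal(a$p_B_hat, a$bit_errors / a$bit_trials)
  expect_equal(a$p_V_hat, a$vector_errors / a$vector_trials)
  expect_lte(a$vector_errors, a$bit_errors)
  expect_equal(a$bit_trials, 20 * 10 * 50)
  # pooled proportion equals the mean of per-realization proportions here
  expect_equal(a$p_B_hat, mean(a$per_realization$p_B))
  expect_error(estimate_retrieval(100, 100, 100, seed = 1, budget = 10),
               "budget")
})

test_that("exhaustive enumeration matches an independent loop oracle", {
  expect_equal(as.numeric(exhaustive_bit_error(3, 2)), 0)
  for (case in list(c(2, 2), c(3, 2), c(2, 4))) {
    for (retain in c(TRUE, FALSE)) {
      expect_equal(as.numeric(exhaustive_bit_error(case[1], case[2], retain)),
                   slow_exhaustive_bit_error(case[1], case[2], retain),
                   tolerance = 1e-14)
    }
  }
  expect_error(exhaustive_bit_error(5, 5), "N \\* P <= 20")
})

test_that("the exact (4,4) bit error is rational and below theory plus margin", {
  x <- exhaustive_bit_error(4, 4)
  total <- attr(x, "total_bit_errors")
  expect_equal(total, round(total))
  expect_equal(as.numeric(x), total / (2^16 * 16))
  expect_gt(as.numeric(x), 0)
  expect_lt(as.numeric(x), p_bit_error(4, 4) + 0.05)
})

test_that("Monte-Carlo converges to the exhaustive value at tiny sizes", {
  # (4,4) and (3,5) lie above the no-noise bound, so the exact value is
  # strictly positive and the binomial standard error is meaningful
  for (case in list(c(4, 4), c(3, 5))) {
    N <- case[1]; P <- case[2]
    exact <- as.numeric(exhaustive_bit_error(N, P))
    est <- estimate_retrieval(N, P, reps = 2e4, seed = 3)
    se <- sqrt(exact * (1 - exact) / est$bit_trials)
    expect_gt(se, 0)
    expect_lt(abs(est$p_B_hat - exact), 4 * se)
  }
})

test_that("fixed-point census enumerates exactly", {
  expect_equal(count_fixed_points(diag(3))$count, 8)
  expect_equal(count_fixed_points(matrix(0, 3, 3))$count, 1)
  cen0 <- count_fixed_points(matrix(0, 3, 3))
  expect_equal(cen0$fixed_states, matrix(1, 1, 3))  # all-plus under sign(0)=+1

  # a single stored pattern yields exactly the pattern and its mirror (odd N)
  for (N in c(5, 7, 9, 11)) {
    xi <- generate_patterns(1, N, seed = N)
    cen <- count_fixed_points(hebbian_matrix(xi))
    expect_equal(cen$count, 2)
    keys <- apply(cen$fixed_states, 1, paste, collapse = ",")
    expect_setequal(keys, c(paste(xi[1, ], collapse = ","),
                            paste(-xi[1, ], collapse = ",")))
  }
  expect_error(count_fixed_points(diag(23)), "N <= 22")
})

test_that("one-step-stable stored patterns appear in the exhaustive census", {
  for (seed in 1:3) {
    xi <- generate_patterns(6, 10, seed = seed)
    net <- hopfield(xi)
    out <- predict(net)
    stable <- which(rowSums(out != xi) == 0)
    cen <- count_fixed_points(net)
    keys <- apply(cen$fixed_states, 1, paste, collapse = ",")
    for (mu in stable) {
      expect_true(paste(xi[mu, ], collapse = ",") %in% keys)
    }
  }
})

test_that("the growth-rate fit recovers a closed-form degenerate slope", {
  # identity couplings: every state fixed, count = 2^N, slope exactly ln 2
  # lm warns that the fit is exact, which is the point here
  g <- suppressWarnings(estimate_gamma(8, 12, reps = 3, seed = 1,
                                       matrix_fn = function(N) diag(N)))
  expect_equal(g$gamma_hat, log(2), tolerance = 1e-10)
  expect_lt(g$se, 1e-10)
  expect_error(estimate_gamma(4, 12, reps = 2, seed = 1), "integer")
  expect_error(estimate_gamma(12, 10, reps = 2, seed = 1), "N_min < N_max")
})

test_that("spurious probes are rejected more often than stored memories", {
  est <- estimate_spurious(50, 50, reps = 200, probes = 50, seed = 7)
  theory <- spurious_error_prob(50, 50, "bit")   # ~ 0.1538
  expect_lt(abs(est$pbar_B_hat - theory),
            max(4 * est$ci_halfwidth_bit, 0.15 * theory))
  expect_identical(est$bit_count,
                   estimate_spurious(50, 50, reps = 200, probes = 50,
                                     seed = 7)$bit_count)

  # at matched (N, P) random probes are rejected at least as often as
  # stored patterns fail (rho > 1)
  ret <- estimate_retrieval(50, 200, reps = 300, seed = 8)
  spu <- estimate_spurious(50, 200, reps = 300, probes = 200, seed = 8)
  expect_gte(spu$pbar_V_hat, ret$p_V_hat)
  # and the measured ratio is within a factor 2 of the exact vector-level
  # prediction at this load
  ratio_theory <- spurious_error_prob(50, 200, "vector") /
    p_vector_error(50, 200)
  ratio_hat <- spu$pbar_V_hat / ret$p_V_hat
  expect_gt(ratio_hat / ratio_theory, 0.5)
  expect_lt(ratio_hat / ratio_theory, 2)
})

test_that("spurious probing reports a domain error when no probe can exist", {
  # at N = 2, 200 random patterns cover all four states
  expect_error(estimate_spurious(2, 200, reps = 1, probes = 1, seed = 1),
               "outside the training set")
})

test_that("capacity sweeps cover the grid with matching analytic fields", {
  grid <- sweep_capacity(c(50, 100), c(10, 100), reps = 20, seed = 2)
  expect_s3_class(grid, "capacity_grid")
  expect_equal(nrow(grid), 4)
  expect_setequal(paste(grid$N, grid$P),
                  c("50 10", "50 100", "100 10", "100 100"))
  expect_equal(grid$p_B_theory, p_bit_error(grid$N, grid$P, TRUE))
  expect_equal(grid$N_V_theory_zero,
               expected_unrecovered(grid$N, grid$P, FALSE))
  # single-cell sweep at P = 1: a stored pattern is always recovered
  g1 <- suppressMessages(sweep_capacity(50, 1, reps = 10, seed = 1))
  expect_equal(g1$p_B_hat, 0)
  # cell-level resource errors carry the offending coordinates
  expect_error(sweep_capacity(c(10, 500), c(10, 500), reps = 100, seed = 1,
                              budget = 1e5),
               "cell \\(N = ")
})
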