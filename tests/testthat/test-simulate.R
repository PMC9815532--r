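test_that("the time grid matches the fixed-step configuration", {
  tr <- simulate_game(baseline)
  expect_equal(nrow(tr), floor(3 / 0.0125) + 1L)
  expect_equal(tr$t[1], 0)
  expect_equal(tr$t[nrow(tr)], 3)
  expect_true(all(as.matrix(tr[, c("x", "y", "z", "w")]) >= 0 &
                  as.matrix(tr[, c("x", "y", "z", "w")]) <= 1))
})

test_that("corners are invariant under integration", {
  for (nm in c("E1", "E13", "E16")) {
    cr <- corner_profiles()[nm, ]
    tr <- simulate_game(baseline, init = cr, t_final = 0.5)
    expect_true(all(apply(tr[, c("x", "y", "z", "w")], 1L,
                          function(r) all(r == cr))))
  }
})

test_that("the baseline run converges to the unique ESS (1, 1, 0, 1)", {
  tr <- simulate_game(baseline)
  final <- as.numeric(tr[nrow(tr), c("x", "y", "z", "w")])
  expect_true(all(abs(final - c(1, 1, 0, 1)) < 0.01))
  # the elderly flow is logistic with positive rate, so w never decreases
  expect_true(all(diff(tr$w) >= 0))
  conv <- detect_converged_strategy(tr, tol = 0.01, window = 40L)
  expect_equal(as.character(conv), c("HQ", "PV", "NR", "ON"))
})

test_that("the fixed-step run agrees with an adaptive reference integration", {
  ref <- deSolve::ode(
    y = c(x = 0.5, y = 0.5, z = 0.5, w = 0.5), times = c(0, 3),
    func = function(t, state, parms)
      list(as.numeric(replicator_rhs(baseline, state))),
    parms = NULL, rtol = 1e-10, atol = 1e-10)
  final_ref <- as.numeric(ref[nrow(ref), -1])
  eu <- simulate_game(baseline, method = "euler")
  rk <- simulate_game(baseline, method = "rk4")
  expect_true(all(abs(as.numeric(eu[nrow(eu), -1]) - final_ref) < 1e-2))
  expect_true(all(abs(as.numeric(rk[nrow(rk), -1]) - final_ref) < 1e-4))
})

test_that("halving the step barely moves the final state, and euler tracks rk4", {
  f1 <- as.numeric(tail(simulate_game(baseline, step = 0.0125), 1)[-1])
  f2 <- as.numeric(tail(simulate_game(baseline, step = 0.00625), 1)[-1])
  expect_true(all(abs(f1 - f2) < 1e-3))
  frk <- as.numeric(tail(simulate_game(baseline, method = "rk4"), 1)[-1])
  expect_true(all(abs(f1 - frk) < 1e-2))
})

test_that("with the other populations frozen, w follows the exact logistic solution", {
  tr <- simulate_game(baseline, init = c(1, 1, 0, 0.5),
                      hold = c("x", "y", "z"), method = "rk4")
  exact <- logistic_w(0.5, baseline$Cm - baseline$Cw, tr$t)
  expect_true(max(abs(tr$w - exact)) < 1e-4)
})

test_that("convergence detection labels constant and oscillating trajectories", {
  const <- simulate_game(baseline, init = c(1, 1, 0, 1), t_final = 1)
  expect_equal(as.character(detect_converged_strategy(const, 0.01, 10L)),
               c("HQ", "PV", "NR", "ON"))
  # an artificial oscillation across 0.5 resolves nothing
  osc <- const
  osc$x <- rep(c(0.4, 0.6), length.out = nrow(osc))
  expect_equal(detect_converged_strategy(osc, 0.01, 10L)[["x"]], "unresolved")
  expect_error(detect_converged_strategy(const, 0.01, 10000L), "window")
})

test_that("time_to_threshold finds the first crossing toward the limit", {
  const <- simulate_game(baseline, init = c(1, 1, 0, 1), t_final = 1)
  expect_equal(time_to_threshold(const, "provider", 0.99), 0)
  tr <- simulate_game(baseline)
  tw <- time_to_threshold(tr, "elderly", 0.99)
  expect_true(is.finite(tw) && tw < 3)
  # logistic closed form: w crosses 0.99 near log(99)/rate
  expect_equal(tw, log(99) / 2, tolerance = 0.05)
  # nondecreasing in the level for a monotone trajectory
  levels <- c(0.6, 0.9, 0.99)
  times <- vapply(levels, function(l) time_to_threshold(tr, "elderly", l),
                  numeric(1))
  expect_true(all(diff(times) >= 0))
  # downward crossing toward the government's limit at 0
  tz <- time_to_threshold(tr, "government", 0.01)
  expect_true(is.finite(tz) && tz > 0 && tz < 3)
  expect_error(time_to_threshold(tr, "elderly", 1.2), "between")
})

test_that("integration rejects bad configurations", {
  expect_error(simulate_game(baseline, step = -1), "positive")
  expect_error(simulate_game(baseline, t_final = -1), "exceed")
  expect_error(simulate_game(baseline, init = c(2, 0, 0, 0)), "\\[0, 1\\]")
  expect_error(simulate_game(baseline, hold = "q"), "hold")
})
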