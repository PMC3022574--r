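test_that("the confined solve converges to the physiological fixed point", {
  sol <- coarse_solution()
  expect_true(sol$convergence$converged)
  res <- sol$convergence$residuals
  expect_lt(abs(res[length(res)]), sol$controls$c0_tolerance)
  expect_gt(sol$edge$c0, 10); expect_lt(sol$edge$c0, 20)
  V <- 60 * sol$edge$V
  expect_gt(V, 10); expect_lt(V, 15)
  expect_gt(sol$edge$r_plus, 0)
})

test_that("the fixed point is independent of the relaxation parameter", {
  ctr1 <- numerical_controls(dx = 0.1, dt = 0.05, dtau = 0.1, damping = 0.5)
  ctr2 <- numerical_controls(dx = 0.1, dt = 0.05, dtau = 0.1, damping = 1)
  p <- actin_parameters()
  s1 <- solve_steady_state(p, ctr1)
  s2 <- solve_steady_state(p, ctr2)
  expect_lt(abs(s1$edge$c0 - s2$edge$c0), 2 * ctr1$c0_tolerance)
})

test_that("doubling the grid resolution moves c(0) by less than 1%", {
  p <- actin_parameters()
  coarse <- solve_steady_state(p, numerical_controls(dx = 0.08, dt = 0.04,
                                                     dtau = 0.08))
  fine <- solve_steady_state(p, numerical_controls(dx = 0.04, dt = 0.02,
                                                   dtau = 0.04))
  expect_lt(abs(coarse$edge$c0 - fine$edge$c0) / fine$edge$c0, 0.01)
})

test_that("a poor starting guess converges to the same fixed point", {
  p <- actin_parameters()
  ctr <- numerical_controls(dx = 0.1, dt = 0.05, dtau = 0.1, c0_initial = 40)
  s <- solve_steady_state(p, ctr)
  ref <- solve_steady_state(p, numerical_controls(dx = 0.1, dt = 0.05,
                                                  dtau = 0.1))
  expect_lt(abs(s$edge$c0 - ref$edge$c0), 2 * ctr$c0_tolerance)
})

test_that("network length interpolates the threshold crossing", {
  prof <- structure(list(x = c(0, 1, 2, 3), F = c(40, 20, 4, 1)),
                    class = "spatial_profiles")
  expect_equal(network_length(prof, 5), 1 + 15 / 16)
  expect_equal(network_length(prof, 100), 0)   # threshold above F(0)
  prof0 <- structure(list(x = c(0, 1), F = c(0, 0)),
                     class = "spatial_profiles")
  expect_equal(network_length(prof0, 5), 0)
  full <- structure(list(x = c(0, 1), F = c(400, 300)),
                    class = "spatial_profiles")
  expect_identical(network_length(full, 5), Inf)
  # confined baseline fills the box
  expect_identical(network_length(coarse_solution()), Inf)
})

test_that("unconfined mode ends the network well before the box", {
  p <- actin_parameters(r_tm = 0, D = 1)
  sol <- solve_steady_state(p, numerical_controls(dx = 0.1, dt = 0.02,
                                                  dtau = 0.2),
                            mode = "unconfined", L_box = 40)
  n <- length(sol$profiles$x)
  expect_lt(sol$profiles$F[n], 1e-3)
  Ln <- network_length(sol)
  expect_true(is.finite(Ln))
  expect_lt(Ln, max(sol$profiles$x))
  # the monomer pool plateaus behind the network
  expect_lt(abs(sol$profiles$c[n] - sol$profiles$c[n - 1]), 1e-3)
})
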