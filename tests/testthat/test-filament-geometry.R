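test_that("plus-end rate reproduces hand-evaluated reference points", {
  p <- actin_parameters()
  expect_equal(plus_end_rate(0, 1, p), -1.4)            # pure off-rate
  cc <- p$k_off_plus / p$k_on_plus                      # 0.11667 uM
  expect_equal(plus_end_rate(cc, 0, p), 0, tolerance = 1e-12)
  f <- filament_force(p$B, p)
  r <- plus_end_rate(15, f, p)
  expect_equal(r, 12 * 15 * exp(-f * 0.0022 / 0.0041) - 1.4)
  expect_gt(r, 95); expect_lt(r, 110)                   # ~103 s^-1
  V <- 60 * p$delta_p * r
  expect_gt(V, 10); expect_lt(V, 15)                    # um/min
})

test_that("edge state couples V, B_eff and the load consistently", {
  p <- actin_parameters()
  e <- edge_state(15, p)
  expect_equal(e$V, p$delta_p * e$r_plus)
  expect_equal(e$B_eff, e$N0 / p$r_cap)
  # fixed nucleation: halving the plus-end pool doubles the load
  p2 <- actin_parameters(r_cap = 2)
  e2 <- edge_state(15, p2, N0_ref = p$B * p$r_cap)
  expect_equal(e2$B_eff, p$B / 2)
  expect_equal(e2$f, 2 * e$f)
})

test_that("filament length matches the constant-rate closed form", {
  p <- actin_parameters()
  edge <- edge_state(15, p)
  r <- 9
  traj <- constant_rate_trajectory(r, t_max = 60, dt = 0.01)
  closed <- function(t_uc, tau_c) {
    pmax(0, p$delta_p * (edge$r_plus * t_uc - r * (t_uc + tau_c)))
  }
  for (tc in c(0, 1, 7.3)) {
    t_uc <- c(0, 0.37, 1, 2.5, 5)
    expect_equal(filament_length(t_uc, tc, edge, traj), closed(t_uc, tc),
                 tolerance = 1e-10)
  }
  expect_equal(filament_length(0, 0, edge, traj), 0)
  # complete depolymerization floors at zero
  expect_equal(filament_length(0.5, 50, edge, traj), 0)
  # grid overrun is a truncation error
  expect_error(filament_length(10, 55, edge, traj), "overrun")
})

test_that("minimal uncapped time inverts the length relation", {
  p <- actin_parameters()
  edge <- edge_state(15, p)
  r <- 9
  traj <- constant_rate_trajectory(r, t_max = 60, dt = 0.01)
  expect_equal(min_uncapped_time(0, 0, edge, traj), 0)
  for (theta in c(0.05, 0.3, 1)) {
    for (tc in c(0, 2, 10)) {
      got <- min_uncapped_time(theta, tc, edge, traj)
      want <- (theta / p$delta_p + r * tc) / (edge$r_plus - r)
      expect_equal(got, want, tolerance = 1e-4)
    }
  }
  # unreachable probe length
  expect_identical(min_uncapped_time(50, 0, edge, traj, t_uc_max = 10), Inf)
})

test_that("inversion agrees with an exhaustive grid-scan oracle", {
  p <- actin_parameters()
  fe <- fixed_edge()
  edge <- fe$edge; traj <- fe$traj
  grid <- seq(0, 15, by = 0.001)
  for (case_ in list(c(0.2, 0), c(0.5, 3), c(1.2, 10))) {
    theta <- case_[1]; tc <- case_[2]
    L <- filament_length(grid, tc, edge, traj)
    oracle <- grid[which(L >= theta)[1]]
    got <- min_uncapped_time(theta, tc, edge, traj)
    expect_lt(abs(got - oracle), 0.002)
  }
})

test_that("minimal uncapped time is nondecreasing in probe length and age", {
  fe <- fixed_edge()
  th <- seq(0, 1.5, by = 0.25)
  t1 <- vapply(th, function(q) min_uncapped_time(q, 1, fe$edge, fe$traj),
               numeric(1))
  expect_true(all(diff(t1) >= 0))
  tc <- seq(0, 20, by = 4)
  t2 <- vapply(tc, function(q) min_uncapped_time(0.4, q, fe$edge, fe$traj),
               numeric(1))
  expect_true(all(diff(t2) >= 0))
})
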