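test_that("state probabilities start at (1,0,0,0) and stay normalized", {
  p <- actin_parameters()
  traj <- subunit_states(p, t_max = 50, dt = 0.01)
  expect_equal(traj$p_atp[1], 1)
  expect_equal(traj$p_adp[1], 0)
  expect_equal(traj$p_ac[1], 0)
  expect_equal(traj$p_tm[1], 0)
  total <- traj$p_atp + traj$p_adp + traj$p_ac + traj$p_tm
  expect_lt(max(abs(total - 1)), 1e-6)
  # structural monotonicities
  expect_true(all(diff(traj$p_atp) < 0))
  expect_true(all(diff(traj$p_tm) >= 0))
  expect_true(all(diff(traj$p_deb) >= 0))
  expect_true(all(diff(traj$S) >= 0))
  expect_equal(traj$S[1], 0)
  expect_equal(traj$r_minus[1], 0)   # p_deb(0) = 0
})

test_that("probability normalization holds across random rate sets", {
  set.seed(42)
  for (i in 1:8) {
    p <- actin_parameters(r_hyd = runif(1, 0.05, 2),
                          r_ac = runif(1, 0.05, 2),
                          r_ac_minus = runif(1, 0, 1),
                          r_tm = runif(1, 0, 1))
    traj <- subunit_states(p, t_max = 20, dt = 0.05)
    total <- traj$p_atp + traj$p_adp + traj$p_ac + traj$p_tm
    expect_lt(max(abs(total - 1)), 1e-6)
    expect_true(all(traj$r_minus_free >= p$k_off_minus - 1e-9))
    expect_true(all(traj$r_minus_free <= p$s_ac * p$k_off_minus + 1e-9))
  }
})

test_that("matrix-exponential propagation matches an adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- actin_parameters()
  traj <- subunit_states(p, t_max = 5, dt = 0.01)
  rhs <- function(t, y, parms) {
    list(c(-p$r_hyd * y[1],
           p$r_hyd * y[1] - (p$r_ac + p$r_tm) * y[2] + p$r_ac_minus * y[3],
           p$r_ac * y[2] - p$r_ac_minus * y[3],
           p$r_tm * y[2]))
  }
  out <- deSolve::lsoda(c(1, 0, 0, 0), times = c(0, 5), func = rhs,
                        rtol = 1e-10, atol = 1e-12)
  n <- length(traj$t)
  expect_equal(c(traj$p_atp[n], traj$p_adp[n], traj$p_ac[n], traj$p_tm[n]),
               unname(out[2, 2:5]), tolerance = 1e-6)
})

test_that("tropomyosin is the unique absorbing state", {
  p <- actin_parameters()
  traj <- subunit_states(p, t_max = 200, dt = 0.05)
  n <- length(traj$t)
  expect_equal(traj$p_tm[n], 1, tolerance = 1e-3)
  # with all subunits TM-bound and debranching complete the minus-end rate
  # reverts to the unenhanced in vitro value
  expect_equal(traj$r_minus[n], p$k_off_minus, tolerance = 0.01)
})

test_that("degenerate kinetic limits behave", {
  p <- actin_parameters(r_hyd = 0)
  traj <- subunit_states(p, t_max = 10, dt = 0.05)
  expect_true(all(traj$p_atp == 1))   # absorbing start state
  # no enhancement + (effectively) instant debranching: r_minus ~ k_off_minus
  p2 <- actin_parameters(s_ac = 1, r_deb = 5000)
  traj2 <- subunit_states(p2, t_max = 5, dt = 0.01)
  expect_equal(traj2$r_minus[-1], rep(p2$k_off_minus, length(traj2$t) - 1),
               tolerance = 1e-6)
  # forced constant-rate trajectory: S is exactly linear
  tc <- constant_rate_trajectory(9, t_max = 10, dt = 0.01)
  expect_equal(tc$S, 9 * tc$t)
})
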