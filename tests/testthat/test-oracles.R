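test_that("constant-rate pipeline matches the closed forms", {
  p <- actin_parameters()
  edge <- edge_state(15, p)
  r <- 9
  ctr <- numerical_controls(dx = 0.05, dt = 0.01, dtau = 0.02)
  L_box <- 12
  traj <- constant_rate_trajectory(r, t_max = 15 / p$r_cap +
                                     1.1 * L_box / edge$V, dt = ctr$dt)
  prof <- network_profiles(edge, traj, p, ctr, L_box = L_box)
  cf <- constant_rate_solution(p, edge, r, prof$x)
  dev1 <- compare_profiles(prof, cf, c("F", "F_uc", "L_mean"), F_floor = 5)
  dev2 <- compare_profiles(prof, cf, c("M", "J_d"), F_floor = 5,
                           x_min = 2 * ctr$dx)
  expect_lt(max(dev1, dev2), 0.05)
  # the analytic structure itself: F = B exp(-(a-b) x)
  a <- p$r_cap / (p$delta_p * (edge$r_plus - r))
  b <- p$r_cap / edge$V
  expect_equal(cf$F, edge$B_eff * exp(-(a - b) * prof$x))
  expect_equal(cf$F_uc, edge$B_eff * exp(-a * prof$x))
  # exact mass balance of the closed form
  expect_equal(cf$J_d, edge$V * (a - b) * cf$F, tolerance = 1e-10)
})

test_that("ensemble quadrature agrees with the group-integral pipeline", {
  fe <- fixed_edge()
  ctr <- numerical_controls(dx = 0.05, dt = 0.01, dtau = 0.02)
  prof <- network_profiles(fe$edge, fe$traj, fe$p, ctr, L_box = 10)
  ens <- ensemble_brute_force(fe$p, fe$edge, fe$traj, prof$x,
                              dt_uc = 0.01, dtau_c = 0.01)
  devF <- compare_profiles(prof, ens, c("F", "L_mean"), F_floor = 5)
  devM <- compare_profiles(prof, ens, c("M", "J_d"), F_floor = 5,
                           x_min = 2 * ctr$dx)
  expect_lt(devF[["F"]], 0.02)
  expect_lt(devF[["L_mean"]], 0.05)
  expect_lt(devM[["M"]], 0.05)
  expect_lt(devM[["J_d"]], 0.05)
})

test_that("ensemble agreement tightens under grid refinement", {
  fe <- fixed_edge()
  ctr <- numerical_controls(dx = 0.1, dt = 0.01, dtau = 0.02)
  prof <- network_profiles(fe$edge, fe$traj, fe$p, ctr, L_box = 6)
  dev_of <- function(h) {
    ens <- ensemble_brute_force(fe$p, fe$edge, fe$traj, prof$x,
                                dt_uc = h, dtau_c = h)
    compare_profiles(prof, ens, "F", F_floor = 5)[["F"]]
  }
  expect_lt(dev_of(0.02), dev_of(0.08))
})

test_that("a degenerate single cohort deposits a rectangle", {
  p <- actin_parameters()
  edge <- edge_state(15, p)
  traj <- constant_rate_trajectory(9, t_max = 30, dt = 0.01)
  x <- seq(0, 4, by = 0.02)
  dt_uc <- 0.02
  t_mid <- seq(dt_uc / 2, 6, by = dt_uc)
  wts <- rep(0, length(t_mid))
  i_star <- which.min(abs(t_mid - 5))       # all capping mass at t_uc ~ 5 s
  wts[i_star] <- 1
  args <- list(p = p, edge = edge, traj = traj, x = x, dt_uc = dt_uc,
               dtau_c = 0.5, t_uc_max = 6, tau_c_max = 0.5)
  ens <- do.call(ensemble_brute_force, c(args, list(t_uc_weights = wts)))
  ens_uc <- do.call(ensemble_brute_force,
                    c(args, list(t_uc_weights = 0 * wts)))
  rect <- ens$F - ens_uc$F                  # capped cohort alone
  tau_star <- 0.25                          # midpoint of the single cell
  t_star <- t_mid[i_star]
  L_star <- p$delta_p * (edge$r_plus * t_star - 9 * (t_star + tau_star))
  lo <- edge$V * tau_star; hi <- lo + L_star
  height <- edge$N0 * 1 * 0.5               # weight * dtau_c
  inside <- x > lo + 0.05 & x < hi - 0.05
  outside <- x < lo - 0.05 | x > hi + 0.05
  expect_true(all(abs(rect[inside] - height) < 1e-9))
  expect_true(all(abs(rect[outside]) < 1e-9))
  # conservation of deposition: integral equals height times width
  expect_equal(pracma::trapz(x, rect), height * L_star, tolerance = 0.02)
})
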