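test_that("group density obeys the Heaviside cut-off and the closed form", {
  p <- actin_parameters()
  edge <- edge_state(15, p)
  r <- 9
  traj <- constant_rate_trajectory(r, t_max = 60, dt = 0.01)
  # ahead of the group's plus-ends the contribution vanishes
  expect_equal(group_density(0.5, 10, edge, traj, p), 0)
  # closed form: N0 exp(-r_cap (theta/delta_p + r tau)/(r_plus - r))
  for (case_ in list(c(1, 0.5), c(2, 3), c(0.3, 0))) {
    x <- case_[1]; tc <- case_[2]
    theta <- x - edge$V * tc
    want <- edge$N0 *
      exp(-p$r_cap * (theta / p$delta_p + r * tc) / (edge$r_plus - r))
    expect_equal(group_density(x, tc, edge, traj, p), want,
                 tolerance = 1e-4)
  }
})

test_that("Poisson capping closure agrees with explicit quadrature", {
  # the group integral N0 int_{t_min}^{inf} r_cap exp(-r_cap t) dt closes to
  # N0 exp(-r_cap t_min); check against numeric quadrature, which also
  # verifies the capping-fraction normalization (t_min = 0 gives N0 back)
  p <- actin_parameters()
  fe <- fixed_edge()
  for (case_ in list(c(0.8, 0.5), c(2.5, 4))) {
    x <- case_[1]; tc <- case_[2]
    t_min <- min_uncapped_time(x - fe$edge$V * tc, tc, fe$edge, fe$traj)
    quad <- stats::integrate(function(t) p$r_cap * exp(-p$r_cap * t),
                             t_min, Inf, rel.tol = 1e-10)$value
    expect_equal(group_density(x, tc, fe$edge, fe$traj, p),
                 fe$edge$N0 * quad, tolerance = 1e-6)
  }
  expect_equal(stats::integrate(function(t) p$r_cap * exp(-p$r_cap * t),
                                0, Inf)$value, 1, tolerance = 1e-9)
})

test_that("profile fields satisfy the structural invariants", {
  sol <- coarse_solution()
  prof <- sol$profiles
  expect_true(all(prof$F >= 0))
  expect_true(all(prof$M >= 0))
  expect_true(all(prof$J_d >= 0))
  expect_equal(prof$F, prof$F_c + prof$F_uc)
  # no polymerization behind the edge: F cannot increase with x
  expect_true(all(diff(prof$F) <= 1e-9))
  expect_true(all(prof$F_ac + prof$F_tm <= prof$F + 1e-9))
  # leading edge: uncapped plus-end density, no capped material, clean ATP
  expect_equal(prof$F_uc[1], sol$edge$B_eff)
  expect_equal(prof$F_c[1], 0)
  expect_equal(prof$F[1], sol$edge$B_eff)
  expect_equal(prof$F_ac[1], 0)
  expect_equal(prof$F_tm[1], 0)
  expect_equal(prof$J_d[1], 0)
})

test_that("mean filament length rises steeply to a rear plateau", {
  sol <- coarse_solution()
  prof <- sol$profiles
  plateau <- prof$L_mean[length(prof$L_mean)]
  expect_gt(plateau, prof$L_mean[1] * 1.5)
  # plateau reached within ~1 um of the edge
  i1 <- which.min(abs(prof$x - 1))
  expect_lt(abs(prof$L_mean[i1] - plateau) / plateau, 0.05)
})

test_that("the depolymerization peak sits between the edge and the rear", {
  prof <- coarse_solution()$profiles
  i <- which.max(prof$J_d)
  expect_gt(prof$x[i], 0.5)
  expect_lt(prof$x[i], 3)
  # single interior maximum: a lightly smoothed J_d (5-cell running mean,
  # suppressing sub-percent cell noise of the differenced minus-end field)
  # rises before and falls after the peak
  Js <- as.numeric(stats::filter(prof$J_d, rep(1 / 5, 5), sides = 2))
  ok <- !is.na(Js)
  Js <- Js[ok]
  is_ <- which.max(Js)
  expect_true(all(diff(Js[1:is_]) >= -1e-3 * max(Js)))
  expect_true(all(diff(Js[is_:length(Js)]) <= 1e-3 * max(Js)))
})

test_that("local and global mass balance hold", {
  sol <- coarse_solution()
  prof <- sol$profiles
  V <- sol$edge$V
  dx <- prof$x[2] - prof$x[1]
  Jd <- prof$J_d
  intJ <- pracma::trapz(prof$x, Jd)
  # global: polymer influx = interior depolymerization + rear dump
  lhs <- V * prof$F[1]
  rhs <- intJ + V * prof$F[length(prof$F)]
  expect_lt(abs(lhs - rhs) / lhs, 0.05)
  # local: J_d ~ -V dF/dx up to the age-mixing approximation
  keep <- prof$x > 0.2
  dFdx <- c(NA, diff(prof$F)) / dx
  resid <- abs(Jd + V * dFdx)
  expect_lt(pracma::trapz(prof$x[keep], resid[keep]), 0.1 * intJ)
})

test_that("length distributions are normalized and consistent with L_mean", {
  sol <- coarse_solution()
  fe <- list(p = sol$params, edge = sol$edge, traj = sol$traj)
  ctr <- sol$controls
  xq <- c(0, 1, 5, 9)
  ld <- length_distribution(xq, fe$edge, fe$traj, fe$p, ctr)
  dL <- ld$L[2] - ld$L[1]
  norms <- colSums(ld$P) * dL
  expect_true(all(abs(norms - 1) < 1e-3))
  expect_true(all(ld$P >= 0))
  idx <- vapply(xq, function(q) which.min(abs(sol$profiles$x - q)),
                integer(1))
  expect_equal(ld$L_mean, sol$profiles$L_mean[idx], tolerance = 0.01)
  # at the edge the distribution is exponential-like: monotone decay and
  # most filaments short
  P0 <- ld$P[, 1]
  expect_gt(sum(P0[ld$L < 0.3]) * dL, 0.6)
  headband <- P0[ld$L < 0.8]
  expect_true(all(diff(headband) < 1e-6))
  # F(x) = 0 is an undefined-distribution error
  expect_error(length_distribution(1e5, fe$edge, fe$traj, fe$p, ctr),
               "undefined")
})

test_that("regulator profiles separate: cofilin front, tropomyosin rear", {
  sol <- coarse_solution()
  prof <- sol$profiles
  reg <- regulator_profiles(prof, sol$traj, sol$edge)
  expect_equal(reg$F_ac, prof$F_ac)
  i_front <- which.min(abs(prof$x - 0.5))
  expect_gt(prof$F_ac[i_front], prof$F_tm[i_front])
  n <- length(prof$x)
  expect_gt(prof$F_tm[n], prof$F_ac[n])
  # tropomyosin knock-out keeps F_tm identically zero
  p0 <- actin_parameters(r_tm = 0)
  e0 <- edge_state(15, p0)
  tr0 <- subunit_states(p0, t_max = 15 / p0$r_cap + 1.1 * 3 / e0$V,
                        dt = 0.02)
  pr0 <- network_profiles(e0, tr0, p0,
                          numerical_controls(dx = 0.1, dt = 0.02,
                                             dtau = 0.1),
                          L_box = 3)
  expect_true(all(pr0$F_tm == 0))
})
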