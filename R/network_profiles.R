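# Spatial fields of the steady-state network.
#
# Filaments sharing the same capped duration tau_c form a "group" whose
# plus-ends sit at x = V * tau_c.  A filament (t_uc, tau_c) spans
# [V tau_c, V tau_c + L(t_uc, tau_c)] and carries Poisson capping weight
# r_cap exp(-r_cap t_uc) dt_uc.  Because L is strictly increasing in t_uc,
# every per-group field reduces to a forward map of the tabulated pairs
# (position reached, survival weight) onto the x grid:
#
#   * crossing concentration  f(x, tau_c) = N0 exp(-r_cap t_uc_min(theta))
#   * surviving minus-ends beyond x      = N0 exp(-r_cap max(t_uc_min, t_death))
#   * length-weighted numerator for L_mean via the reverse cumulative
#     integral W(t) = int_t^tmax r_cap e^{-r_cap u} L(u) du.
#
# The minus-end concentration is recovered from the cumulative count by
# backward differencing (equivalent to binning minus-end positions into the
# spatial cells), and the depolymerization source density is
# J_d(x) = M(x) * r_minus(x / V) under the age ~ x/V identification.

# Interpolate tabulated (pos, val) onto the x grid: ahead of the first
# tabulated position the first value extends (the group's full surviving
# weight); beyond the last position the field is zero (no filament
# reaches).
forward_map <- function(pos, val, x) {
  if (length(pos) < 2L) return(numeric(length(x)))
  y <- stats::approx(pos, val, xout = x, rule = c(2, 1), ties = "ordered")$y
  y[is.na(y)] <- 0
  y
}

# Trapezoid end-point weight over the capped-time grid (the far end decays
# below the survival cutoff, so only the tau = 0 boundary needs the 1/2).
trapz_wt <- function(k, K_max) if (k == 0L) 0.5 else 1

#' Build all spatial profiles of the filament network
#'
#' Integrates the capped filament groups (trapezoid over the capped time,
#' adaptively truncated) and the single uncapped group into the F-actin
#' concentration (total, capped, uncapped), the minus-end concentration,
#' the depolymerization source density, the mean filament length, and the
#' ADF/cofilin- and tropomyosin-bound F-actin profiles.
#'
#' @param edge an [edge_state()] for the current solver iterate.
#' @param traj a `subunit_trajectory` covering ages up to
#'   `t_uc_max + tau_c_max`.
#' @param p an [actin_parameters()] object.
#' @param controls a [numerical_controls()] object.
#' @param L_box spatial extent of the solution box, um (defaults to
#'   `p$L_sys`; unconfined drivers pass larger boxes).
#' @return An object of class `spatial_profiles` with the x grid and fields
#'   `F`, `F_c`, `F_uc`, `M`, `J_d` (uM, uM/s), `L_mean` (um), `F_ac`,
#'   `F_tm` (uM) and a `c` slot filled by [solve_monomer_profile()].
#'   Attributes carry truncation diagnostics.
#' @export
network_profiles <- function(edge, traj, p, controls, L_box = p$L_sys) {
  stopifnot(inherits(edge, "edge_state"), inherits(traj, "subunit_trajectory"),
            inherits(p, "actin_parameters"),
            inherits(controls, "numerical_controls"))
  V <- edge$V; rp <- edge$r_plus
  if (rp <= 0) stop_infeasible("non-positive plus-end rate")
  dt <- traj$dt; dx <- controls$dx
  x <- seq(0, L_box, by = dx)
  nx <- length(x)
  n_uc <- round(resolve_t_uc_max(controls, p) / dt)
  nS <- length(traj$S)
  if (n_uc + 1L > nS) {
    stop("trajectory grid shorter than the uncapped-time horizon",
         call. = FALSE)
  }
  t_uc <- traj$t[seq_len(n_uc + 1L)]
  if (rp <= max(traj$r_minus)) {
    stop_infeasible("plus-end rate does not dominate the minus-end rate; filament length not monotone")
  }
  w <- exp(-p$r_cap * t_uc)
  m <- round(controls$dtau / dt)
  dtau <- m * dt
  # admissible number of capped groups: grid availability, box support and
  # optional explicit cap
  K_grid <- (nS - (n_uc + 1L)) %/% m
  K_box <- floor(L_box / (V * dtau))
  K_max <- min(K_grid, K_box)
  if (!is.null(controls$tau_c_max)) {
    K_max <- min(K_max, floor(controls$tau_c_max / dtau))
  }
  delta_p <- p$delta_p
  N0 <- edge$N0
  F_c <- numeric(nx); Cmin <- numeric(nx); Lnum <- numeric(nx)
  last_surv <- 1; K_used <- 0L; truncated <- FALSE
  S <- traj$S
  half <- V * dtau / 2
  for (k in 0:K_max) {
    off <- k * m
    idx <- off + seq_len(n_uc + 1L)
    L <- delta_p * (rp * t_uc - S[idx])
    alive <- L > 0
    alive[1L] <- alive[1L] || k == 0L   # t_uc = 0, L = 0 boundary point
    ia <- which(alive)[1L]
    if (is.na(ia)) { last_surv <- 0; K_used <- k; break }
    surv <- w[ia]
    last_surv <- surv; K_used <- k
    if (surv < controls$survival_cutoff) break
    xk <- V * k * dtau
    pos <- xk + L[ia:(n_uc + 1L)]
    yv <- w[ia:(n_uc + 1L)]
    g <- p$r_cap * w * pmax(L, 0)
    Wfull <- trapz_uniform(g, dt) - cumtrapz_uniform(g, dt)
    wt <- N0 * dtau
    # partial-cell handling of the capped-time integral's upper support
    # limit tau = x/V: each group's tau cell enters with its overlap
    # fraction, a linear ramp across the cell, so the integral stays
    # continuous in x instead of a staircase of group switch-ons
    ramp <- if (k == 0L) {
      0.5 * pmin(x / half, 1)
    } else {
      pmin(pmax((x - xk + half) / (2 * half), 0), 1)
    }
    F_c <- F_c + wt * ramp * forward_map(pos, yv, x)
    Cmin <- Cmin + wt * trapz_wt(k, K_max) * forward_map(pos, yv, x)
    Lnum <- Lnum + wt * ramp * forward_map(pos, Wfull[ia:(n_uc + 1L)], x)
  }
  if (K_used == K_max && last_surv >= controls$survival_cutoff &&
      K_grid <= K_box) {
    truncated <- TRUE
    if (last_surv > 1e-6) {
      warning("capped-time integration truncated while groups still carry ",
              signif(last_surv, 3), " relative survival; extend the ",
              "trajectory horizon or tau_c_max", call. = FALSE)
    }
  }
  # single uncapped group (plus-ends at x = 0), weight B_eff
  L0 <- delta_p * (rp * t_uc - S[seq_len(n_uc + 1L)])
  g0 <- p$r_cap * w * pmax(L0, 0)
  W0 <- trapz_uniform(g0, dt) - cumtrapz_uniform(g0, dt)
  F_uc <- edge$B_eff * forward_map(L0, w, x)
  Cmin <- Cmin + edge$B_eff * forward_map(L0, w, x)
  Lnum <- Lnum + edge$B_eff * forward_map(L0, W0, x)
  FF <- F_c + F_uc
  # minus ends per cell by backward differencing of the cumulative count;
  # one minus end counts like one subunit in its delta_p-thick slab
  M <- numeric(nx)
  if (nx > 1L) M[2:nx] <- delta_p * (Cmin[1:(nx - 1L)] - Cmin[2:nx]) / dx
  M[M < 0] <- 0
  r_at_x <- stats::approx(traj$t, traj$r_minus, xout = pmin(x / V, max(traj$t)),
                          rule = 2)$y
  J_d <- M * r_at_x
  L_mean <- ifelse(FF > 0, Lnum / FF, NA_real_)
  p_ac_x <- stats::approx(traj$t, traj$p_ac, xout = pmin(x / V, max(traj$t)),
                          rule = 2)$y
  p_tm_x <- stats::approx(traj$t, traj$p_tm, xout = pmin(x / V, max(traj$t)),
                          rule = 2)$y
  structure(list(x = x, F = FF, F_c = F_c, F_uc = F_uc, M = M, J_d = J_d,
                 L_mean = L_mean, F_ac = FF * p_ac_x, F_tm = FF * p_tm_x,
                 c = rep(NA_real_, nx)),
            class = "spatial_profiles",
            tau_c_max_used = K_used * dtau, dtau = dtau,
            truncated = truncated, last_survival = last_surv)
}

stop_infeasible <- function(msg) {
  cond <- structure(class = c("actintread_infeasible", "error", "condition"),
                    list(message = msg, call = NULL))
  stop(cond)
}

#' @export
print.spatial_profiles <- function(x, ...) {
  cat(sprintf("Spatial profiles on [0, %g] um (%d points)\n",
              max(x$x), length(x$x)))
  cat(sprintf("  F(0) = %.4g uM, min F = %.4g uM, max J_d = %.4g uM/s\n",
              x$F[1], min(x$F), max(x$J_d)))
  if (!all(is.na(x$c))) {
    cat(sprintf("  c(0) = %.4g uM, c(rear) = %.4g uM\n",
                x$c[1], x$c[length(x$c)]))
  }
  invisible(x)
}

#' @export
as.data.frame.spatial_profiles <- function(x, ...) {
  data.frame(x = x$x, F = x$F, F_uc = x$F_uc, F_c = x$F_c, M = x$M,
             J_d = x$J_d, c = x$c, L_mean = x$L_mean, F_ac = x$F_ac,
             F_tm = x$F_tm)
}

#' F-actin concentration profile
#'
#' Convenience wrapper around [network_profiles()] exposing the capped,
#' uncapped, and total F-actin concentration fields.
#' @inheritParams network_profiles
#' @return A `spatial_profiles` object (see [network_profiles()]).
#' @export
f_actin_profile <- function(edge, traj, p, controls, L_box = p$L_sys) {
  network_profiles(edge, traj, p, controls, L_box)
}

#' Minus-end concentration profile
#'
#' @inheritParams network_profiles
#' @return Numeric vector `M(x)` (uM) on the grid of the profiles.
#' @export
minus_end_profile <- function(edge, traj, p, controls, L_box = p$L_sys) {
  network_profiles(edge, traj, p, controls, L_box)$M
}

#' Depolymerization source density
#'
#' `J_d(x) = M(x) * r_minus(x / V)`: minus-end concentration times the
#' ensemble-averaged minus-end rate at the age `x / V` of material at `x`.
#'
#' @param profiles a `spatial_profiles` object (for `M` and the grid).
#' @param traj the `subunit_trajectory` used to build the profiles.
#' @param edge the corresponding [edge_state()].
#' @return Numeric vector `J_d(x)` in uM/s.
#' @export
depolymerization_density <- function(profiles, traj, edge) {
  r_at_x <- stats::approx(traj$t, traj$r_minus,
                          xout = pmin(profiles$x / edge$V, max(traj$t)),
                          rule = 2)$y
  profiles$M * r_at_x
}

#' Regulator-bound F-actin profiles
#'
#' ADF/cofilin- and tropomyosin-bound F-actin concentrations under the
#' dwell-time ~ age ~ x/V identification:
#' `F_ac(x) = F(x) p_ac(x/V)`, `F_tm(x) = F(x) p_tm(x/V)`.
#'
#' @inheritParams depolymerization_density
#' @return A data frame with columns `x`, `F_ac`, `F_tm` (uM).
#' @export
regulator_profiles <- function(profiles, traj, edge) {
  age <- pmin(profiles$x / edge$V, max(traj$t))
  p_ac_x <- stats::approx(traj$t, traj$p_ac, xout = age, rule = 2)$y
  p_tm_x <- stats::approx(traj$t, traj$p_tm, xout = age, rule = 2)$y
  data.frame(x = profiles$x, F_ac = profiles$F * p_ac_x,
             F_tm = profiles$F * p_tm_x)
}

#' Filament length distribution at given positions
#'
#' For each requested position the length distribution of the filaments
#' transecting it is assembled from all capped groups plus the uncapped
#' group, each weighted by its share of the local F-actin concentration.
#' The complementary cumulative distribution closes group-wise through the
#' Poisson capping statistics and is differenced onto the length grid.
#'
#' @param x_query positions, um (scalar or vector).
#' @inheritParams network_profiles
#' @param L_grid length bin edges, um; defaults to steps of `10 * delta_p`
#'   up to the maximal reachable length.
#' @return An object of class `length_distribution`: list with `x`
#'   (positions), `L` (bin midpoints, um), `P` (matrix, densities per um,
#'   one column per position), and `L_mean` (um, one entry per position).
#' @export
length_distribution <- function(x_query, edge, traj, p, controls,
                                L_grid = NULL) {
  stopifnot(all(x_query >= 0))
  V <- edge$V; rp <- edge$r_plus
  dt <- traj$dt
  n_uc <- round(resolve_t_uc_max(controls, p) / dt)
  t_uc <- traj$t[seq_len(n_uc + 1L)]
  w <- exp(-p$r_cap * t_uc)
  if (is.null(L_grid)) {
    L_grid <- seq(0, p$delta_p * rp * t_uc[n_uc + 1L], by = 10 * p$delta_p)
  }
  m <- round(controls$dtau / dt)
  dtau <- m * dt
  nS <- length(traj$S)
  K_grid <- (nS - (n_uc + 1L)) %/% m
  S <- traj$S
  nq <- length(x_query)
  CCDF <- matrix(0, nrow = length(L_grid), ncol = nq)
  Fx <- numeric(nq)
  half <- V * dtau / 2
  for (k in 0:K_grid) {
    idx <- k * m + seq_len(n_uc + 1L)
    L <- p$delta_p * (rp * t_uc - S[idx])
    alive <- L > 0
    alive[1L] <- alive[1L] || k == 0L
    ia <- which(alive)[1L]
    if (is.na(ia)) break
    if (w[ia] < controls$survival_cutoff) break
    xk <- V * k * dtau
    wt <- edge$N0 * dtau
    Lal <- L[ia:(n_uc + 1L)]; wal <- w[ia:(n_uc + 1L)]
    for (j in seq_len(nq)) {
      # overlap fraction of this tau cell with [0, x/V] (see
      # network_profiles); groups wholly ahead of x contribute nothing
      ramp <- if (k == 0L) {
        0.5 * min(x_query[j] / half, 1)
      } else {
        min(max((x_query[j] - xk + half) / (2 * half), 0), 1)
      }
      if (ramp <= 0) next
      theta <- max(x_query[j] - xk, 0)
      qv <- pmax(L_grid, theta)
      cc <- stats::approx(Lal, wal, xout = qv, rule = c(2, 1),
                          ties = "ordered")$y
      cc[is.na(cc)] <- 0
      CCDF[, j] <- CCDF[, j] + wt * ramp * cc
      Fx[j] <- Fx[j] + wt * ramp * cc[1L]
    }
  }
  # uncapped group
  L0 <- p$delta_p * (rp * t_uc - S[seq_len(n_uc + 1L)])
  for (j in seq_len(nq)) {
    qv <- pmax(L_grid, x_query[j])
    cc <- stats::approx(L0, w, xout = qv, rule = c(2, 1), ties = "ordered")$y
    cc[is.na(cc)] <- 0
    CCDF[, j] <- CCDF[, j] + edge$B_eff * cc
    Fx[j] <- Fx[j] + edge$B_eff * cc[1L]
  }
  if (any(Fx <= 0)) {
    stop("length distribution undefined where F(x) = 0", call. = FALSE)
  }
  dL <- diff(L_grid)
  P <- sweep(-apply(CCDF, 2L, diff) / dL, 2L, Fx, "/")
  P[P < 0] <- 0
  L_mid <- (L_grid[-1L] + L_grid[-length(L_grid)]) / 2
  # E[L] = int CCDF dL / F since L >= 0
  L_mean <- apply(CCDF, 2L, function(cc) {
    sum((cc[-1L] + cc[-length(cc)]) / 2 * dL)
  }) / Fx
  structure(list(x = x_query, L = L_mid, P = P, L_mean = L_mean, F_x = Fx),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("Filament length distribution at %d position(s)\n",
              length(x$x)))
  for (j in seq_along(x$x)) {
    cat(sprintf("  x = %-8g L_mean = %.4g um\n", x$x[j], x$L_mean[j]))
  }
  invisible(x)
}
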