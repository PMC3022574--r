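# Subunit state kinetics.
#
# An F-actin subunit enters a filament in the ATP state and then moves
# through the state graph ATP -> ADP <-> ADF/cofilin-bound, ADP -> TM-bound:
#
#   p_atp' = -r_hyd p_atp
#   p_adp' =  r_hyd p_atp - (r_ac + r_tm) p_adp + r_ac_minus p_ac
#   p_ac'  =  r_ac  p_adp - r_ac_minus p_ac
#   p_tm'  =  r_tm  p_adp
#
# with initial state (1, 0, 0, 0).  Tropomyosin binding is irreversible on
# turnover time scales, so TM is the unique absorbing state whenever
# r_tm > 0 and r_ac_minus > 0.  The system is linear; the matrix
# exponential is evaluated in closed form through the eigendecomposition
# of the generator (no error accumulation along the grid), with a
# substepped RK4 integration as fallback for (near-)defective generators.

state_rate_matrix <- function(p) {
  matrix(c(-p$r_hyd, 0,                        0,            0,
            p$r_hyd, -(p$r_ac + p$r_tm),       p$r_ac_minus, 0,
            0,        p$r_ac,                 -p$r_ac_minus, 0,
            0,        p$r_tm,                  0,            0),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("atp", "adp", "ac", "tm"), NULL))
}

#' Solve the F-actin subunit state probabilities
#'
#' Propagates the four-state linear kinetics (ATP, ADP, ADF/cofilin-bound,
#' tropomyosin-bound) of a subunit from its addition at the plus-end over a
#' uniform time grid, and attaches the filament-level debranching and
#' capping-survival probabilities.
#'
#' @param p an [actin_parameters()] object.
#' @param t_max grid horizon, s.
#' @param dt grid step, s.
#' @return An object of class `subunit_trajectory` with fields `t` (s), the
#'   state probabilities `p_atp`, `p_adp`, `p_ac`, `p_tm`, the debranching
#'   probability `p_deb = 1 - exp(-r_deb t)`, the uncapped-survival
#'   probability `p_uc = exp(-r_cap t)`, and (after [minus_end_rate()],
#'   which is applied automatically) the free and effective minus-end rates
#'   and the cumulative shrinkage `S` in subunits.
#' @examples
#' traj <- subunit_states(actin_parameters(), t_max = 30, dt = 0.01)
#' traj$p_atp[1]   # 1: subunits are added ATP-bound
#' @export
subunit_states <- function(p, t_max, dt = 0.01) {
  stopifnot(inherits(p, "actin_parameters"), t_max > 0, dt > 0)
  n <- ceiling(t_max / dt - 1e-9)
  t <- seq(0, by = dt, length.out = n + 1L)
  Q <- state_rate_matrix(p)
  probs <- tryCatch(state_probs_eigen(Q, t), error = function(e) NULL)
  if (is.null(probs)) probs <- state_probs_rk4(Q, t, dt)
  traj <- structure(list(
    t = t, dt = dt,
    p_atp = probs[, 1L], p_adp = probs[, 2L],
    p_ac = probs[, 3L], p_tm = probs[, 4L],
    p_deb = 1 - exp(-p$r_deb * t),
    p_uc = exp(-p$r_cap * t)
  ), class = "subunit_trajectory")
  minus_end_rate(traj, p)
}

# p(t) = V exp(diag(lambda) t) V^{-1} e1, evaluated for the whole grid at
# once.  Errors (and thereby triggers the RK4 fallback) when the
# eigendecomposition is unusable.
state_probs_eigen <- function(Q, t) {
  eg <- eigen(Q)
  coef <- solve(eg$vectors)[, 1L]          # V^{-1} e1
  probs <- Re(t(eg$vectors %*% (exp(outer(eg$values, t)) * coef)))
  if (max(abs(probs[1L, ] - c(1, 0, 0, 0))) > 1e-9 ||
      max(abs(rowSums(probs) - 1)) > 1e-9 ||
      min(probs) < -1e-9) {
    stop("eigendecomposition inaccurate")
  }
  pmin(pmax(probs, 0), 1)
}

# Classic RK4 on the linear system, substepped so that the step stays well
# inside the stability/accuracy region of the fastest rate.
state_probs_rk4 <- function(Q, t, dt) {
  n <- length(t)
  m <- max(1L, ceiling(dt * max(abs(diag(Q))) / 0.05))
  h <- dt / m
  probs <- matrix(0, nrow = n, ncol = 4L)
  v <- c(1, 0, 0, 0)
  probs[1L, ] <- v
  for (i in seq_len(n - 1L)) {
    for (s in seq_len(m)) {
      k1 <- Q %*% v
      k2 <- Q %*% (v + h / 2 * k1)
      k3 <- Q %*% (v + h / 2 * k2)
      k4 <- Q %*% (v + h * k3)
      v <- v + h / 6 * as.vector(k1 + 2 * k2 + 2 * k3 + k4)
    }
    probs[i + 1L, ] <- v
  }
  pmin(pmax(probs, 0), 1)
}

#' Minus-end dissociation rate along a state trajectory
#'
#' The free minus-end rate weighs the unenhanced off-rate (ATP, ADP and
#' tropomyosin-bound terminal subunits) against the ADF/cofilin-enhanced
#' off-rate; the effective rate multiplies it by the debranching probability
#' (only debranched filaments depolymerize).  Under the dwell-time ~ age
#' identification the resulting rate depends on the time since nucleation
#' only.  The cumulative shrinkage `S(t)` (subunits lost from the minus end
#' by age `t`) is accumulated with the trapezoidal rule.
#'
#' @param traj a `subunit_trajectory`.
#' @param p an [actin_parameters()] object.
#' @return `traj` with `r_minus_free`, `r_minus` (s^-1) and `S` (subunits)
#'   filled in.
#' @export
minus_end_rate <- function(traj, p) {
  stopifnot(inherits(traj, "subunit_trajectory"))
  free <- p$k_off_minus * (traj$p_atp + traj$p_adp + traj$p_tm) +
    p$s_ac * p$k_off_minus * traj$p_ac
  eff <- traj$p_deb * free
  traj$r_minus_free <- free
  traj$r_minus <- eff
  traj$S <- cumtrapz_uniform(eff, traj$dt)
  traj
}

# Trapezoidal cumulative integral on a uniform grid (fast path used in all
# hot loops; pracma::cumtrapz is equivalent but allocates a matrix).
cumtrapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((y[-n] + y[-1L]) * 0.5 * dt))
}

# Plain trapezoid on a uniform grid.
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-n] + y[-1L]) * 0.5) * dt
}

#' Synthetic trajectory with a constant minus-end rate
#'
#' Builds a `subunit_trajectory` whose effective minus-end rate is the
#' constant `r_const` for all ages (`S(t) = r_const * t`).  This is the
#' simplified scenario of immediate hydrolysis, debranching, and
#' ADF/cofilin binding without tropomyosin, for which the full spatial
#' pipeline admits closed-form solutions and which therefore serves as a
#' verification input (see [constant_rate_solution()]).
#'
#' @param r_const constant minus-end rate, s^-1.
#' @param t_max,dt grid horizon and step, s.
#' @return A `subunit_trajectory` with degenerate state probabilities
#'   (all mass in the ADF/cofilin state) and `r_minus` constant.
#' @export
constant_rate_trajectory <- function(r_const, t_max, dt = 0.01) {
  stopifnot(r_const > 0, t_max > 0, dt > 0)
  n <- ceiling(t_max / dt - 1e-9)
  t <- seq(0, by = dt, length.out = n + 1L)
  one <- rep(1, n + 1L)
  structure(list(
    t = t, dt = dt,
    p_atp = 0 * one, p_adp = 0 * one, p_ac = one, p_tm = 0 * one,
    p_deb = one, p_uc = NA_real_,
    r_minus_free = r_const * one,
    r_minus = r_const * one,
    S = r_const * t
  ), class = "subunit_trajectory")
}

#' @export
print.subunit_trajectory <- function(x, ...) {
  cat(sprintf("Subunit state trajectory: %d points, dt = %g s, t_max = %g s\n",
              length(x$t), x$dt, max(x$t)))
  if (!is.null(x$r_minus)) {
    cat(sprintf("  r_minus range [%.4g, %.4g] s^-1, S(t_max) = %.4g subunits\n",
                min(x$r_minus), max(x$r_minus), x$S[length(x$S)]))
  }
  invisible(x)
}

#' @export
as.data.frame.subunit_trajectory <- function(x, ...) {
  data.frame(t = x$t, p_atp = x$p_atp, p_adp = x$p_adp, p_ac = x$p_ac,
             p_tm = x$p_tm, p_deb = x$p_deb,
             r_minus_free = x$r_minus_free, r_minus = x$r_minus, S = x$S)
}

#' Export a subunit trajectory as CSV
#'
#' @param traj a `subunit_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
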