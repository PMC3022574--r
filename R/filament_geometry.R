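# Filament-level geometry: thermal-ratchet plus-end rate, edge state,
# filament length as a function of uncapped/capped times, and inversion to
# the minimal uncapped time needed to reach a probe length.

#' Net plus-end polymerization rate under membrane load
#'
#' Thermal-ratchet force-velocity relation for monomer addition at an
#' uncapped plus-end pressing against the membrane:
#' `r_plus = k_on_plus * c0 * exp(-f * delta_p / kBT) - k_off_plus`.
#'
#' @param c0 G-actin concentration at the leading edge, uM.
#' @param f load per filament, pN.
#' @param p an [actin_parameters()] object.
#' @return Net subunit addition rate, s^-1 (may be negative below the
#'   force-shifted critical concentration).
#' @examples
#' p <- actin_parameters()
#' plus_end_rate(15, filament_force(p$B, p), p)
#' @export
plus_end_rate <- function(c0, f, p) {
  stopifnot(all(c0 >= 0), all(f >= 0))
  p$k_on_plus * c0 * exp(-f * p$delta_p / p$kBT) - p$k_off_plus
}

#' Coupled leading-edge variables for one solver iterate
#'
#' Bundles the edge quantities that close the model at `x = 0`: the G-actin
#' concentration `c0`, the per-filament load `f`, the plus-end rate
#' `r_plus`, the network growth rate `V = delta_p * r_plus`, the nucleation
#' rate `N0` and the effective plus-end density `B_eff = N0 / r_cap`.
#'
#' By default `N0` is derived from the supplied parameter set as
#' `B * r_cap`.  Passing an explicit `N0_ref` (uM/s) instead holds the
#' nucleation rate at a reference value while `B_eff` and `f` respond to
#' `r_cap` — the behaviour used in capping-rate scans, where fewer pushing
#' filaments each carry a higher load.
#'
#' @param c0 leading-edge G-actin concentration, uM.
#' @param p an [actin_parameters()] object.
#' @param N0_ref optional fixed nucleation rate, uM s^-1.
#' @return An object of class `edge_state`.
#' @export
edge_state <- function(c0, p, N0_ref = NULL) {
  stopifnot(c0 >= 0)
  N0 <- if (is.null(N0_ref)) p$B * p$r_cap else N0_ref
  B_eff <- N0 / p$r_cap
  f <- filament_force(B_eff, p)
  rp <- plus_end_rate(c0, f, p)
  structure(list(c0 = c0, f = f, r_plus = rp, V = p$delta_p * rp,
                 N0 = N0, B_eff = B_eff, delta_p = p$delta_p),
            class = "edge_state")
}

#' @export
print.edge_state <- function(x, ...) {
  cat(sprintf(paste0("Edge state: c0 = %.4g uM, f = %.4g pN, ",
                     "r_plus = %.4g s^-1, V = %.4g um/s (%.3g um/min), ",
                     "N0 = %.4g uM/s, B_eff = %.4g uM\n"),
              x$c0, x$f, x$r_plus, x$V, 60 * x$V, x$N0, x$B_eff))
  invisible(x)
}

# Linear interpolation of the cumulative shrinkage S at arbitrary ages.
# S is tabulated on the uniform trajectory grid; querying beyond the grid is
# a truncation error.
interp_S <- function(traj, t_query) {
  tmax <- traj$t[length(traj$t)]
  if (any(t_query > tmax + 1e-9)) {
    stop("trajectory grid overrun: requested age ", max(t_query),
         " s exceeds the tabulated horizon ", tmax,
         " s (truncation); extend t_max", call. = FALSE)
  }
  stats::approx(traj$t, traj$S, xout = pmin(t_query, tmax), rule = 2)$y
}

#' Filament length from its uncapped and capped times
#'
#' A filament grows only while uncapped (`r_plus * t_uc` subunits) and
#' shrinks from its minus end throughout its life
#' (`S(t_uc + tau_c)` subunits).  The x-projected length is
#' `L = delta_p * (r_plus * t_uc - S(t_uc + tau_c))`, floored at zero
#' (a fully depolymerized filament is gone).
#'
#' @param t_uc uncapped duration(s), s.
#' @param tau_c capped duration, s (scalar or vector conformable with `t_uc`).
#' @param edge an [edge_state()].
#' @param traj a `subunit_trajectory` with `S` filled.
#' @return x-projected length(s), um.
#' @export
filament_length <- function(t_uc, tau_c, edge, traj) {
  stopifnot(all(t_uc >= 0), all(tau_c >= 0))
  S <- interp_S(traj, t_uc + tau_c)
  pmax(0, edge$delta_p * (t_uc * edge$r_plus - S))
}

#' Minimal uncapped time to reach a probe length
#'
#' Inverts the monotone length relation: the smallest `t_uc` with
#' `L(t_uc, tau_c) >= theta`.  Monotonicity in `t_uc` holds whenever the
#' plus-end rate exceeds every realized minus-end rate, which is the case
#' for physiological parameters.  The inverse is found by bracketing on the
#' trajectory grid followed by bisection on the linear interpolant of `S`,
#' accurate to well below 1e-4 um in `L`.
#'
#' @param theta probe length, um (>= 0).
#' @param tau_c capped duration, s.
#' @param edge an [edge_state()].
#' @param traj a `subunit_trajectory`.
#' @param t_uc_max horizon, s; `Inf` is returned if `theta` is not reached
#'   by `t_uc_max` (or within the trajectory grid).
#' @return Minimal uncapped time, s (possibly `Inf`).
#' @export
min_uncapped_time <- function(theta, tau_c, edge, traj,
                              t_uc_max = max(traj$t) - tau_c) {
  stopifnot(theta >= 0, tau_c >= 0, edge$r_plus > 0)
  if (theta == 0 && tau_c == 0) return(0)
  tmax <- min(t_uc_max, max(traj$t) - tau_c)
  if (tmax <= 0) return(Inf)
  Lfun <- function(t_uc) filament_length(t_uc, tau_c, edge, traj)
  if (Lfun(tmax) < theta) return(Inf)
  lo <- 0; hi <- tmax
  # bracket on the grid first (L is piecewise linear between grid ages)
  tg <- traj$t - tau_c
  tg <- tg[tg >= 0 & tg <= tmax]
  if (length(tg) > 2L) {
    Lg <- Lfun(tg)
    i <- findInterval(theta, Lg)        # Lg nondecreasing
    if (i >= 1L && i < length(tg)) { lo <- tg[i]; hi <- tg[i + 1L] }
  }
  for (k in 1:60) {
    mid <- 0.5 * (lo + hi)
    if (Lfun(mid) >= theta) hi <- mid else lo <- mid
    if (hi - lo < 1e-9) break
  }
  hi
}

#' F-actin group density from the capping statistics
#'
#' With Poisson capping, the concentration contribution (per unit capped
#' time) of the filament group with capped duration `tau_c` at position `x`
#' closes to `N0 * exp(-r_cap * t_uc_min(theta, tau_c))` for
#' `theta = x - V tau_c >= 0`, and zero ahead of the group's plus-ends
#' (Heaviside cut-off).
#'
#' @param x position, um.
#' @param tau_c capped duration of the group, s.
#' @param edge an [edge_state()].
#' @param traj a `subunit_trajectory`.
#' @param p an [actin_parameters()] object.
#' @return Group density, uM s^-1.
#' @export
group_density <- function(x, tau_c, edge, traj, p) {
  theta <- x - edge$V * tau_c
  if (theta < 0) return(0)
  t_min <- min_uncapped_time(theta, tau_c, edge, traj)
  if (!is.finite(t_min)) return(0)
  edge$N0 * exp(-p$r_cap * t_min)
}
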