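# Fixed-point solution of the coupled steady state.
#
# One iterate maps the leading-edge G-actin concentration through the whole
# model: c(0) -> plus-end rate -> growth rate V -> filament groups ->
# F(x), M(x), J_d(x) -> diffusion -> output c(0).  Damped substitution on
# c(0) closes the loop; convergence is declared when input and output agree
# to the fixed-point tolerance (50 nM by default).

#' Solve the treadmilling steady state
#'
#' @param p an [actin_parameters()] object.
#' @param controls a [numerical_controls()] object.  For unconfined runs a
#'   spatial step up to 0.1 um and a coarser `dtau` are customary.
#' @param mode `"confined"` (network fills the box, convergence zone at
#'   `L_sys`) or `"unconfined"` (box enlarged until the network ends well
#'   before the boundary).
#' @param N0_ref optional fixed nucleation rate (uM/s) passed to
#'   [edge_state()]; used by capping-rate scans.
#' @param L_box initial box size, um (defaults to `p$L_sys` confined and
#'   60 um unconfined).
#' @param traj optional pre-built or forced `subunit_trajectory` (e.g. a
#'   [constant_rate_trajectory()]); it is extended automatically if too
#'   short unless it was user-supplied, in which case a grid overrun is an
#'   error.
#' @param c0_start optional warm-start value for `c(0)`, uM (overrides
#'   `controls$c0_initial`; used by scans).
#' @param quiet suppress per-iteration progress.
#' @return An object of class `treadmill_solution`: list with `edge`
#'   ([edge_state()]), `profiles` ([network_profiles()] with `c` filled),
#'   `params`, `controls`, `mode`, and `convergence` (iterations, residual
#'   history, tolerance, truncation diagnostics).
#' @examples
#' \donttest{
#' sol <- solve_steady_state(actin_parameters(),
#'                           numerical_controls(dx = 0.05, dt = 0.02))
#' sol$edge$c0
#' }
#' @export
solve_steady_state <- function(p, controls = numerical_controls(),
                               mode = c("confined", "unconfined"),
                               N0_ref = NULL, L_box = NULL, traj = NULL,
                               c0_start = NULL, quiet = TRUE) {
  mode <- match.arg(mode)
  validate_parameters(p)
  user_traj <- !is.null(traj)
  if (is.null(L_box)) L_box <- if (mode == "confined") p$L_sys else 60
  if (mode == "unconfined") {
    repeat {
      sol <- solve_box(p, controls, mode, N0_ref, L_box, traj, c0_start,
                       user_traj, quiet)
      F_rear <- sol$profiles$F[length(sol$profiles$x)]
      if (F_rear < 1e-3) return(sol)
      L_box <- L_box * 1.5
      c0_start <- sol$edge$c0
      if (!quiet) message("rear F-actin ", signif(F_rear, 3),
                          " uM > 1e-3; enlarging box to ", L_box, " um")
    }
  }
  solve_box(p, controls, mode, N0_ref, L_box, traj, c0_start, user_traj,
            quiet)
}

solve_box <- function(p, controls, mode, N0_ref, L_box, traj, c0_start,
                      user_traj, quiet) {
  t_uc_max <- resolve_t_uc_max(controls, p)
  c0 <- if (!is.null(c0_start)) c0_start else controls$c0_initial
  residuals <- numeric(0)
  c0_hist <- numeric(0)
  damping <- controls$damping
  converged <- FALSE
  last <- NULL
  # The residual map res(c0) = c0_out - c0_in is strictly decreasing (a
  # higher edge concentration speeds up growth, lengthens the network, and
  # through the total-actin closure depresses the returned concentration)
  # and its slope near the root is typically far below -1, so plain damped
  # substitution is divergent.  The iteration therefore damps only until a
  # sign change is bracketed and then switches to Illinois-weighted regula
  # falsi inside the bracket; the converged root is independent of the
  # damping parameter.
  lo <- c(NA_real_, NA_real_)   # c0 with res > 0, its residual
  hi <- c(NA_real_, NA_real_)   # c0 with res < 0, its residual
  side <- 0L
  for (it in seq_len(controls$max_iterations)) {
    step <- tryCatch({
      edge <- edge_state(c0, p, N0_ref = N0_ref)
      if (edge$r_plus <= 0) stop_infeasible("non-positive plus-end rate")
      tau_need <- min(L_box / edge$V,
                      controls$tau_c_max %||% Inf)
      traj <- ensure_trajectory(traj, p, t_uc_max + tau_need, controls$dt,
                                user_traj)
      prof <- network_profiles(edge, traj, p, controls, L_box)
      prof <- solve_monomer_profile(prof, p, controls, mode, edge$V)
      list(edge = edge, prof = prof)
    }, actintread_infeasible = function(e) e)
    if (inherits(step, "actintread_infeasible")) {
      # c(0) too low to sustain growth dominating depolymerization: raise it
      c0 <- if (is.na(hi[1L])) c0 * 1.3 else 0.5 * (c0 + hi[1L])
      c0_hist <- c(c0_hist, c0); residuals <- c(residuals, NA_real_)
      next
    }
    c0_out <- attr(step$prof, "c0_out")
    res <- c0_out - c0
    residuals <- c(residuals, res)
    c0_hist <- c(c0_hist, c0)
    last <- step
    if (!quiet) message(sprintf("iter %2d: c0 = %8.4f -> %8.4f uM", it, c0,
                                c0_out))
    if (abs(res) < controls$c0_tolerance) { converged <- TRUE; break }
    if (res > 0) {
      if (is.na(lo[1L]) || c0 > lo[1L]) lo <- c(c0, res)
      if (side == 1L && !is.na(hi[1L])) hi[2L] <- hi[2L] * 0.5
      side <- 1L
    } else {
      if (is.na(hi[1L]) || c0 < hi[1L]) hi <- c(c0, res)
      if (side == -1L && !is.na(lo[1L])) lo[2L] <- lo[2L] * 0.5
      side <- -1L
    }
    if (!is.na(lo[1L]) && !is.na(hi[1L])) {
      # regula falsi with Illinois weighting on the stale endpoint
      c0 <- (lo[1L] * hi[2L] - hi[1L] * lo[2L]) / (hi[2L] - lo[2L])
      span <- hi[1L] - lo[1L]
      c0 <- min(max(c0, lo[1L] + 1e-3 * span), hi[1L] - 1e-3 * span)
    } else {
      c0 <- max(c0 + damping * res, 0.05 * c0)
    }
  }
  if (!converged) {
    stop("fixed-point iteration did not converge within ",
         controls$max_iterations, " iterations; residual trace: ",
         paste(signif(utils::tail(residuals, 5), 3), collapse = ", "),
         call. = FALSE)
  }
  structure(list(edge = last$edge, profiles = last$prof, params = p,
                 controls = controls, mode = mode, L_box = L_box,
                 traj = traj,
                 convergence = list(
                   converged = TRUE, iterations = length(residuals),
                   residuals = residuals, c0_history = c0_hist,
                   tolerance = controls$c0_tolerance,
                   tau_c_max_used = attr(last$prof, "tau_c_max_used"),
                   truncated = attr(last$prof, "truncated"))),
            class = "treadmill_solution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ensure_trajectory <- function(traj, p, t_need, dt, user_traj) {
  if (is.null(traj)) return(subunit_states(p, t_max = 1.05 * t_need, dt = dt))
  if (max(traj$t) >= t_need) return(traj)
  if (user_traj) {
    stop("supplied trajectory grid (t_max = ", max(traj$t),
         " s) is shorter than the required horizon ", signif(t_need, 4),
         " s", call. = FALSE)
  }
  subunit_states(p, t_max = 1.05 * t_need, dt = dt)
}

#' @export
print.treadmill_solution <- function(x, ...) {
  cat(sprintf("Treadmilling steady state (%s, box %g um)\n", x$mode,
              x$L_box))
  cat(sprintf("  converged in %d iterations (|residual| %.3g uM)\n",
              x$convergence$iterations,
              abs(utils::tail(x$convergence$residuals, 1))))
  cat(sprintf("  c(0) = %.4g uM,  V = %.4g um/min,  F(0) = %.4g uM\n",
              x$edge$c0, 60 * x$edge$V, x$profiles$F[1]))
  Lnet <- network_length(x$profiles)
  cat(sprintf("  network length (F < 5 uM): %s\n",
              if (is.finite(Lnet)) sprintf("%.4g um", Lnet)
              else "beyond the box (confined)"))
  invisible(x)
}

#' Network length from the F-actin profile
#'
#' Distance from the leading edge at which the F-actin concentration first
#' drops below the threshold (linearly interpolated between grid points).
#' Returns `Inf` when the concentration never crosses the threshold within
#' the box (a confined network filling the system).
#'
#' @param profiles a `spatial_profiles` object or a `treadmill_solution`.
#' @param threshold concentration threshold, uM (default 5).
#' @return Network length, um (possibly `Inf`; 0 if `F(0)` is already below
#'   the threshold).
#' @export
network_length <- function(profiles, threshold = 5) {
  if (inherits(profiles, "treadmill_solution")) profiles <- profiles$profiles
  stopifnot(threshold > 0)
  FF <- profiles$F; x <- profiles$x
  below <- which(FF < threshold)
  if (!length(below)) return(Inf)
  i <- below[1L]
  if (i == 1L) return(0)
  x[i - 1L] + (threshold - FF[i - 1L]) * (x[i] - x[i - 1L]) /
    (FF[i] - FF[i - 1L])
}
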