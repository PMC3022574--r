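# Steady-state monomer diffusion.
#
# D c''(x) = -J_d(x): monomers released by depolymerization diffuse towards
# the consuming leading edge.  Double cumulative trapezoid of J_d builds the
# particular solution; the rear-gradient condition fixes the first
# integration constant (confined: D c'(L_sys) = V F(L_sys), the convergence
# zone dumps arriving polymer into the monomer pool; unconfined:
# c'(rear) = 0, no flux), and the total-actin closure mean(c + F) = A fixes
# the second.

#' Solve the steady-state G-actin profile
#'
#' @param profiles a `spatial_profiles` object carrying `x`, `F` and `J_d`.
#' @param p an [actin_parameters()] object.
#' @param controls a [numerical_controls()] object (unused beyond
#'   consistency checks; the grid comes with `profiles`).
#' @param mode `"confined"` (rear influx `V F(L_sys)`) or `"unconfined"`
#'   (zero rear gradient).
#' @param V network growth rate used in the rear boundary condition, um/s.
#' @return `profiles` with the `c` field filled; attribute `c0_out` carries
#'   the resulting leading-edge G-actin concentration (the fixed-point
#'   output value).  Negative concentrations anywhere raise an
#'   infeasible-iterate condition that the solver catches.
#' @export
solve_monomer_profile <- function(profiles, p, controls,
                                  mode = c("confined", "unconfined"), V) {
  mode <- match.arg(mode)
  x <- profiles$x
  dx <- x[2L] - x[1L]
  J <- profiles$J_d
  g <- cumtrapz_uniform(J, dx)          # int_0^x J_d
  G <- cumtrapz_uniform(g, dx)          # int_0^x int_0^x' J_d
  L <- x[length(x)]
  rear_flux <- if (mode == "confined") V * profiles$F[length(x)] else 0
  c1 <- (rear_flux + g[length(x)]) / p$D          # c'(0)
  # closure: mean over the box of (c + F) equals the total actin A
  c0 <- p$A - mean_trapz(profiles$F, dx, L) -
    c1 * mean_trapz(x, dx, L) + mean_trapz(G, dx, L) / p$D
  cx <- c0 + c1 * x - G / p$D
  profiles$c <- cx
  attr(profiles, "c0_out") <- c0
  if (any(cx < 0)) {
    attr(profiles, "c_negative") <- TRUE
  }
  profiles
}

mean_trapz <- function(y, dx, L) {
  trapz_uniform(y, dx) / L
}
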