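# Parameter sweeps and derived statistics.
#
# All capping-rate scans hold the nucleation rate N0 at its baseline value:
# a higher capping rate then means fewer pushing filaments (B_eff = N0 /
# r_cap) each under a higher membrane load, which is what couples capping
# to the thermal-ratchet slowdown.

#' Capping-rate x ADF/cofilin-binding-rate scan
#'
#' Unconfined steady states without tropomyosin (`r_tm = 0`) over a grid of
#' plus-end capping rates and ADF/cofilin binding rates, reporting the
#' network length and growth rate per cell.
#'
#' @param p baseline [actin_parameters()] (the scan forces `r_tm = 0`).
#' @param controls [numerical_controls()] used per cell (coarse grids are
#'   customary: `dx = 0.1`, `dtau >= 0.1`).
#' @param r_cap_values,r_ac_values scan axes, s^-1.
#' @param deactivation `"on"` keeps the baseline ADF/cofilin unbinding
#'   rate; `"off"` sets `r_ac_minus = 0` (no deactivation).
#' @param L_box initial box size per cell, um.
#' @param quiet suppress progress messages.
#' @return An object of class `scan_result`: data frame with one row per
#'   cell (`r_cap`, `r_ac`, `L_net` (um), `V` (um/min), `c0` (uM),
#'   `converged`).
#' @export
capping_cofilin_scan <- function(p, controls, r_cap_values, r_ac_values,
                                 deactivation = c("on", "off"),
                                 L_box = 60, quiet = TRUE) {
  deactivation <- match.arg(deactivation)
  stopifnot(all(r_cap_values > 0), all(r_ac_values > 0))
  N0_ref <- p$B * p$r_cap
  grid <- expand.grid(r_ac = r_ac_values, r_cap = r_cap_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  c0_warm <- NULL
  for (i in seq_len(nrow(grid))) {
    pi_ <- actin_parameters(within_list(p, list(
      r_cap = grid$r_cap[i], r_ac = grid$r_ac[i], r_tm = 0,
      r_ac_minus = if (deactivation == "off") 0 else p$r_ac_minus)))
    rows[[i]] <- scan_cell(pi_, controls, N0_ref, L_box, c0_warm, quiet)
    if (rows[[i]]$converged) c0_warm <- rows[[i]]$c0
  }
  out <- cbind(grid[, c("r_cap", "r_ac")], do.call(rbind, rows))
  structure(out, class = c("scan_result", "data.frame"),
            axes = c("r_cap", "r_ac"), deactivation = deactivation)
}

within_list <- function(p, repl) {
  q <- unclass(p)
  q[names(repl)] <- repl
  q
}

scan_cell <- function(p_cell, controls, N0_ref, L_box, c0_warm, quiet) {
  sol <- tryCatch(
    solve_steady_state(p_cell, controls, mode = "unconfined",
                       N0_ref = N0_ref, L_box = L_box, c0_start = c0_warm,
                       quiet = TRUE),
    error = function(e) e)
  if (inherits(sol, "error")) {
    if (!quiet) message("cell failed: ", conditionMessage(sol))
    return(data.frame(L_net = NA_real_, V = NA_real_, c0 = NA_real_,
                      converged = FALSE))
  }
  data.frame(L_net = network_length(sol, controls$length_threshold),
             V = 60 * sol$edge$V, c0 = sol$edge$c0, converged = TRUE)
}

#' Diffusion-coefficient scan with power-law fits
#'
#' Unconfined steady states without tropomyosin across a set of G-actin
#' diffusion coefficients; the network length and growth rate follow power
#' laws in `D`, recovered here by log-log least squares.
#'
#' @param p baseline [actin_parameters()] (the scan forces `r_tm = 0`).
#' @param controls [numerical_controls()] per cell.
#' @param D_values diffusion coefficients, um^2/s (at least half a decade of
#'   span; at least 4 convergent points are required for the fits).
#' @param L_box initial box size, um.
#' @param quiet suppress progress messages.
#' @return A list of class `diffusion_scan`: `table` (a `scan_result`),
#'   `fit_L` and `fit_V` ([fit_power_law()] objects for the network length
#'   and the growth rate).
#' @export
diffusion_scan <- function(p, controls, D_values = c(1, 2, 3, 5, 7, 10),
                           L_box = 60, quiet = TRUE) {
  stopifnot(length(D_values) >= 2,
            max(D_values) / min(D_values) >= sqrt(10))
  N0_ref <- p$B * p$r_cap
  rows <- vector("list", length(D_values))
  c0_warm <- NULL
  for (i in order(D_values)) {
    pi_ <- actin_parameters(within_list(p, list(D = D_values[i], r_tm = 0)))
    rows[[i]] <- scan_cell(pi_, controls, N0_ref, L_box, c0_warm, quiet)
    if (rows[[i]]$converged) c0_warm <- rows[[i]]$c0
    if (!quiet) message("D = ", D_values[i], ": L_net = ",
                        signif(rows[[i]]$L_net, 4), " um")
  }
  tab <- cbind(data.frame(D = D_values), do.call(rbind, rows))
  ok <- tab$converged & is.finite(tab$L_net)
  if (sum(ok) < 4) stop("fewer than 4 converged scan points; fit refused",
                        call. = FALSE)
  fit_L <- fit_power_law(tab$D[ok], tab$L_net[ok])
  fit_V <- fit_power_law(tab$D[ok], tab$V[ok])
  structure(list(table = structure(tab, class = c("scan_result",
                                                  "data.frame"),
                                   axes = "D"),
                 fit_L = fit_L, fit_V = fit_V),
            class = "diffusion_scan")
}

#' Least-squares power-law fit
#'
#' Fits `y = prefactor * x^exponent` by ordinary least squares on
#' `log y ~ log x`.
#'
#' @param x,y positive numeric vectors.
#' @return Object of class `power_law_fit`: list with `exponent`,
#'   `prefactor`, `r_squared` and `range` (the x fit range).
#' @export
fit_power_law <- function(x, y) {
  stopifnot(length(x) == length(y), all(x > 0), all(y > 0))
  fit <- stats::lm(log(y) ~ log(x))
  # suppressWarnings: summary.lm warns on an exactly collinear (perfect) fit
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(exponent = unname(stats::coef(fit)[2L]),
                 prefactor = exp(unname(stats::coef(fit)[1L])),
                 r_squared = r2,
                 range = range(x)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law y = %.4g * x^%.4g (R^2 = %.4f, x in [%g, %g])\n",
              x$prefactor, x$exponent, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Diffusion coefficient producing a target network length
#'
#' Root-finds the unconfined (tropomyosin-free) network length over the
#' diffusion coefficient.
#'
#' @param p baseline [actin_parameters()].
#' @param controls [numerical_controls()].
#' @param target target network length, um (default 10, the lamellum scale).
#' @param interval search interval for `D`, um^2/s.
#' @param tol absolute tolerance on `D`, um^2/s.
#' @param L_box initial box size, um.
#' @return The diffusion coefficient, um^2/s.
#' @export
find_diffusion_for_length <- function(p, controls, target = 10,
                                      interval = c(0.2, 3), tol = 0.01,
                                      L_box = 40) {
  N0_ref <- p$B * p$r_cap
  c0_warm <- new.env(parent = emptyenv())
  c0_warm$v <- NULL
  fn <- function(D) {
    pi_ <- actin_parameters(within_list(p, list(D = D, r_tm = 0)))
    sol <- solve_steady_state(pi_, controls, mode = "unconfined",
                              N0_ref = N0_ref, L_box = L_box,
                              c0_start = c0_warm$v, quiet = TRUE)
    c0_warm$v <- sol$edge$c0
    network_length(sol, controls$length_threshold) - target
  }
  stats::uniroot(fn, interval = interval, tol = tol)$root
}

#' Regulator-effect characterization
#'
#' Confined steady states across ADF/cofilin and tropomyosin binding rates,
#' reporting for each the position of the depolymerization peak (a proxy
#' for the lamellipodial-zone width), the network growth rate, and the
#' polymerized-actin fraction.
#'
#' @param p baseline [actin_parameters()].
#' @param controls [numerical_controls()].
#' @param r_ac_values,r_tm_values scanned binding rates, s^-1 (each axis is
#'   scanned with the other parameter at its baseline value).
#' @param quiet suppress progress messages.
#' @return A tidy data frame with columns `parameter`, `value`,
#'   `J_d_peak_x` (um), `V` (um/min), `F_fraction`, `converged`.
#' @export
regulator_effect_report <- function(p, controls,
                                    r_ac_values = numeric(0),
                                    r_tm_values = numeric(0),
                                    quiet = TRUE) {
  one <- function(param, value) {
    pi_ <- actin_parameters(within_list(p, stats::setNames(list(value),
                                                           param)))
    sol <- tryCatch(solve_steady_state(pi_, controls, mode = "confined",
                                       quiet = TRUE),
                    error = function(e) e)
    if (inherits(sol, "error")) {
      return(data.frame(parameter = param, value = value,
                        J_d_peak_x = NA_real_, V = NA_real_,
                        F_fraction = NA_real_, converged = FALSE))
    }
    prof <- sol$profiles
    dx <- prof$x[2L] - prof$x[1L]
    intF <- trapz_uniform(prof$F, dx)
    intc <- trapz_uniform(prof$c, dx)
    data.frame(parameter = param, value = value,
               J_d_peak_x = prof$x[which.max(prof$J_d)],
               V = 60 * sol$edge$V,
               F_fraction = intF / (intF + intc),
               converged = TRUE)
  }
  out <- rbind(
    do.call(rbind, lapply(r_ac_values, function(v) one("r_ac", v))),
    do.call(rbind, lapply(r_tm_values, function(v) one("r_tm", v))))
  rownames(out) <- NULL
  out
}
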