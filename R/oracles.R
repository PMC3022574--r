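# Independent verification paths.
#
# (a) Constant minus-end rate r: every ingredient is elementary,
#     L(t_uc, tau_c) = delta_p ((r_plus - r) t_uc - r tau_c),
#     t_uc_min(theta, tau_c) = (theta / delta_p + r tau_c) / (r_plus - r),
#     and the capped-group integral closes:
#       F_uc(x) = B exp(-a x),            a = r_cap / (delta_p (r_plus - r))
#       F_c(x)  = B exp(-a x) (exp(b x) - 1),   b = r_cap / V
#       F(x)    = B exp(-(a - b) x)
#       M(x)    = B r_cap / (r_plus - r) exp(-(a - b) x)
#     with exact mass balance J_d = M r = -V F'.
#     Group mean lengths follow from the memoryless excess-life property:
#     crossers of a group exceed the probe length theta by an
#     Exp(r_cap)-distributed number of growth steps, so the local mean
#     length only needs a 1D quadrature over the capped-time weights.
#
# (b) Brute-force ensemble: deterministic quadrature over (t_uc, tau_c)
#     cells depositing each filament cohort's span and minus end onto the
#     spatial grid — an independent discretization of the same model, free
#     of the t_uc inversion used by the pipeline.

#' Closed-form profiles for a constant minus-end rate
#'
#' @param p an [actin_parameters()] object.
#' @param edge an [edge_state()].
#' @param r_const the constant minus-end rate, s^-1; must lie in
#'   `(0, r_plus)`.
#' @param x positions, um.
#' @param L_grid optional length-bin edges (um) at which complementary
#'   cumulative length distributions are also returned for each `x`.
#' @return A list with `x`, `F`, `F_uc`, `F_c`, `M`, `J_d`, `L_mean` and,
#'   if `L_grid` is given, a matrix `CCDF` (one column per position,
#'   crossing-concentration units) from which length histograms follow by
#'   differencing.
#' @export
constant_rate_solution <- function(p, edge, r_const, x, L_grid = NULL) {
  rp <- edge$r_plus; V <- edge$V
  stopifnot(r_const > 0, r_const < rp)
  B <- edge$B_eff
  a <- p$r_cap / (p$delta_p * (rp - r_const))
  b <- p$r_cap / V
  F_uc <- B * exp(-a * x)
  F_c <- B * exp(-a * x) * (exp(b * x) - 1)
  FF <- B * exp(-(a - b) * x)
  M <- B * p$r_cap / (rp - r_const) * exp(-(a - b) * x)
  J_d <- M * r_const
  # mean length: for the group tau_c crossing x (theta = x - V tau_c >= 0)
  # the crossers' mean length is theta + delta_p (r_plus - r) / r_cap; the
  # group weights are f(x, tau) = N0 exp(-a x) exp(r_cap tau) on
  # tau in [0, x/V] plus the uncapped group at theta = x.
  excess <- p$delta_p * (rp - r_const) / p$r_cap
  L_mean <- vapply(x, function(xi) {
    if (xi == 0) return(excess)
    tau <- seq(0, xi / V, length.out = 513L)
    wgt <- exp(p$r_cap * tau)              # common exp(-a x) factor cancels
    theta <- xi - V * tau
    num <- pracma::trapz(tau, wgt * (theta + excess)) * p$r_cap +
      1 * (xi + excess)                    # uncapped group, weight B e^{-ax}
    den <- pracma::trapz(tau, wgt) * p$r_cap + 1
    num / den
  }, numeric(1))
  out <- list(x = x, F = FF, F_uc = F_uc, F_c = F_c, M = M, J_d = J_d,
              L_mean = L_mean)
  if (!is.null(L_grid)) {
    # crossers of group tau with length >= l (l >= theta):
    # survival exp(-r_cap t(l)) with t(l) = (l/delta_p + r tau)/(r_plus - r)
    CCDF <- vapply(x, function(xi) {
      tau <- seq(0, xi / V, length.out = 513L)
      theta <- xi - V * tau
      vapply(L_grid, function(l) {
        tl <- (pmax(l, theta) / p$delta_p + r_const * tau) / (rp - r_const)
        capped <- p$r_cap * pracma::trapz(tau, exp(-p$r_cap * tl))
        t0 <- pmax(l, xi) / (p$delta_p * (rp - r_const))
        B * (capped + exp(-p$r_cap * t0))
      }, numeric(1))
    }, numeric(length(L_grid)))
    out$CCDF <- matrix(CCDF, nrow = length(L_grid))
    out$L_grid <- L_grid
  }
  out
}

#' Brute-force filament-ensemble quadrature
#'
#' Explicit deterministic double loop over (uncapped time, capped time)
#' cells.  Each cell carries the Poisson capping weight
#' `N0 r_cap exp(-r_cap t_uc) dt_uc dtau_c`, spans
#' `[V tau_c, V tau_c + L]`, and deposits its subunit span and its minus
#' end onto the spatial grid.  Completely independent of the group-integral
#' pipeline's minimal-uncapped-time inversion; used as the arbitrating
#' oracle for `F`, `M`, `J_d` and `L_mean`.
#'
#' @param p an [actin_parameters()] object.
#' @param edge an [edge_state()].
#' @param traj a `subunit_trajectory`.
#' @param x positions (uniform grid), um.
#' @param dt_uc,dtau_c quadrature steps, s.
#' @param t_uc_max,tau_c_max quadrature horizons, s.
#' @param t_uc_weights optional override of the uncapped-time cell weights
#'   (length `t_uc_max / dt_uc`, replacing the Poisson capping density;
#'   used to probe degenerate single-group inputs).
#' @return A list with `x`, `F`, `M`, `J_d`, `L_mean`, and the total
#'   deposited subunit integral `total_subunits` (uM um).
#' @export
ensemble_brute_force <- function(p, edge, traj, x, dt_uc = 0.05,
                                 dtau_c = 0.05,
                                 t_uc_max = 15 / p$r_cap,
                                 tau_c_max = NULL,
                                 t_uc_weights = NULL) {
  V <- edge$V; rp <- edge$r_plus
  dx <- x[2L] - x[1L]
  nx <- length(x)
  L_box <- x[nx]
  if (is.null(tau_c_max)) tau_c_max <- L_box / V
  t_mid <- seq(dt_uc / 2, t_uc_max, by = dt_uc)
  w_uc <- if (is.null(t_uc_weights)) {
    p$r_cap * exp(-p$r_cap * t_mid) * dt_uc
  } else {
    stopifnot(length(t_uc_weights) == length(t_mid))
    t_uc_weights
  }
  tau_mid <- seq(dtau_c / 2, tau_c_max, by = dtau_c)
  Fdep <- numeric(nx); Mdep <- numeric(nx); Ldep <- numeric(nx)
  total <- 0
  St <- function(tq) stats::approx(traj$t, traj$S, xout = tq, rule = 2)$y
  if (max(t_mid) + max(tau_mid) > max(traj$t) + 1e-9) {
    stop("trajectory horizon too short for the requested quadrature",
         call. = FALSE)
  }
  deposit <- function(start, ends, wts) {
    # spans [start, ends_i]: F contribution wts_i at every grid point inside
    o <- order(ends)
    ends <- ends[o]; wts <- wts[o]
    rw <- rev(cumsum(rev(wts)))          # total weight with end >= ends[i]
    idx <- findInterval(x - 1e-12, ends) + 1L  # first end >= x
    contrib <- ifelse(idx <= length(ends), rw[pmin(idx, length(ends))], 0)
    contrib[x < start] <- 0
    contrib
  }
  # capped cohorts
  for (j in seq_along(tau_mid)) {
    tau <- tau_mid[j]
    L <- p$delta_p * (rp * t_mid - St(t_mid + tau))
    alive <- L > 0
    if (!any(alive)) next
    wts <- edge$N0 * w_uc[alive] * dtau_c
    La <- L[alive]
    start <- V * tau
    ends <- start + La
    Fdep <- Fdep + deposit(start, ends, wts)
    Ldep <- Ldep + deposit(start, ends, wts * La)
    Mdep <- Mdep + minus_end_bins(ends, wts, dx, nx, p$delta_p)
    total <- total + sum(wts * La)
  }
  # uncapped cohort: plus-ends at 0, number density N0 exp(-r_cap t) dt
  w0 <- edge$N0 * exp(-p$r_cap * t_mid) * dt_uc
  L0 <- p$delta_p * (rp * t_mid - St(t_mid))
  alive <- L0 > 0
  if (any(alive)) {
    Fdep <- Fdep + deposit(0, L0[alive], w0[alive])
    Ldep <- Ldep + deposit(0, L0[alive], w0[alive] * L0[alive])
    Mdep <- Mdep + minus_end_bins(L0[alive], w0[alive], dx, nx, p$delta_p)
    total <- total + sum(w0[alive] * L0[alive])
  }
  r_at_x <- stats::approx(traj$t, traj$r_minus, xout = pmin(x / V, max(traj$t)),
                          rule = 2)$y
  list(x = x, F = Fdep, M = Mdep, J_d = Mdep * r_at_x,
       L_mean = ifelse(Fdep > 0, Ldep / Fdep, NA_real_),
       total_subunits = total)
}

tabulate_weighted <- function(bins, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bins)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# Minus ends deposited onto backward cells (x_{j-1}, x_j] (the pipeline's
# backward-differencing convention) with cloud-in-cell linear sharing
# between the two nearest cell centers, which suppresses the aliasing a
# plain histogram of discrete cohort positions produces on the grid.  A
# minus end counts like one subunit in its delta_p-thick slab.
minus_end_bins <- function(pos, w, dx, nx, delta_p) {
  inb <- pos > 1e-12 & pos <= (nx - 1L) * dx + 1e-12
  if (!any(inb)) return(numeric(nx))
  s <- pos[inb] / dx + 1.5              # cell-centre coordinate of cell j
  j_lo <- floor(s)
  w_hi <- s - j_lo
  out <- tabulate_weighted(pmin(pmax(j_lo, 1L), nx), w[inb] * (1 - w_hi),
                           nx) +
    tabulate_weighted(pmin(pmax(j_lo + 1L, 1L), nx), w[inb] * w_hi, nx)
  (delta_p / dx) * out
}

#' Compare profile fields between two solution routes
#'
#' Maximum relative deviation of selected fields over the region where the
#' reference F-actin concentration stays above a floor (relative errors are
#' meaningless where the network has essentially ended).
#'
#' @param a,b lists with an `x` grid and common numeric fields (pipeline
#'   and oracle output).
#' @param fields character vector of field names to compare.
#' @param F_floor concentration floor, uM, defining the comparison region
#'   via `b$F >= F_floor`.
#' @param x_min lower end of the comparison region, um (cell-convention
#'   differences make the first grid cell of binned minus-end fields
#'   incomparable, so `M`/`J_d` comparisons typically start at `2 dx`).
#' @param rel_floor per-field floor, as a fraction of the field maximum,
#'   below which points are excluded (relative deviations of vanishing
#'   quantities are meaningless).
#' @return Named numeric vector of maximum relative deviations (fractions),
#'   with attribute `region` giving the x range compared.
#' @export
compare_profiles <- function(a, b, fields = c("F", "L_mean"), F_floor = 5,
                             x_min = 0, rel_floor = 1e-3) {
  stopifnot(length(a$x) == length(b$x))
  keep <- b$F >= F_floor & b$x >= x_min
  out <- vapply(fields, function(f) {
    av <- a[[f]][keep]; bv <- b[[f]][keep]
    floor_f <- rel_floor * max(abs(bv), na.rm = TRUE)
    ok <- is.finite(av) & is.finite(bv) & abs(bv) > floor_f
    max(abs(av[ok] - bv[ok]) / abs(bv[ok]))
  }, numeric(1))
  attr(out, "region") <- range(b$x[keep])
  out
}
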