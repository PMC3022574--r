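# Model constants and numerical controls.
#
# All quantities carry fixed units: lengths in micrometres, times in seconds,
# concentrations in micromolar, forces in piconewtons.  The conversion factor
# eta = 602.2 uM^-1 um^-3 between micromolar and molecules per cubic
# micrometre is a physical constant and may not be overridden.

ETA_UM3_PER_UM <- 602.2

.param_defaults <- function() {
  list(
    k_on_plus   = 12,      # uM^-1 s^-1, monomer on-rate at uncapped plus-ends
    k_off_plus  = 1.4,     # s^-1, subunit off-rate at uncapped plus-ends
    k_off_minus = 0.3,     # s^-1, ADP-actin off-rate at free minus-ends
    s_ac        = 30,      # minus-end off-rate enhancement by bound ADF/cofilin
    L_sys       = 10,      # um, extent of the lamellipodium/lamellum
    h           = 0.17,    # um, sheet height of the extension
    delta_p     = 0.0022,  # um, x-projected length gain per subunit (filaments at +-35 deg)
    D           = 5,       # um^2 s^-1, G-actin diffusion coefficient
    A           = 350,     # uM, mean total (F+G) actin over the system
    B           = 440,     # uM, growing plus-end density at the leading edge
    F_mem       = 100,     # pN um^-1, membrane resistance per unit edge length
    r_cap       = 1,       # s^-1, plus-end capping rate
    r_ac        = 0.5,     # s^-1, ADF/cofilin binding rate to ADP-F-actin
    r_ac_minus  = 0.2,     # s^-1, ADF/cofilin unbinding (deactivation) rate
    r_tm        = 0.2,     # s^-1, tropomyosin binding rate to ADP-F-actin
    r_hyd       = 0.3,     # s^-1, hydrolysis + Pi release cascade
    r_deb       = 0.5,     # s^-1, debranching rate
    eta         = ETA_UM3_PER_UM,  # uM^-1 um^-3, fixed unit conversion
    kBT         = 4.1e-3   # pN um, thermal energy at ~298 K
  )
}

# Rates that may legitimately be zero in model variants (e.g. tropomyosin
# knocked out, ADF/cofilin deactivation switched off, instantaneous-kinetics
# limits probed through very large values are still finite and positive).
.zero_ok <- c("r_tm", "r_ac_minus", "r_hyd", "r_deb", "r_ac", "k_off_plus",
              "k_off_minus")

#' Model parameters for the treadmilling-network model
#'
#' Constructs the full set of biophysical constants of the model.  Defaults
#' are the literature-derived reference values for migrating keratocytes;
#' any field can be overridden by name, except the unit conversion factor
#' `eta`, which is fixed at 602.2 per micromolar per cubic micrometre.
#'
#' @param ... named overrides of individual fields (see
#'   [actin_parameter_names()] for the valid names).
#' @return An object of class `actin_parameters`: a named list with fields
#'   `k_on_plus` (uM^-1 s^-1), `k_off_plus`, `k_off_minus`, `r_cap`, `r_ac`,
#'   `r_ac_minus`, `r_tm`, `r_hyd`, `r_deb` (all s^-1), `s_ac`
#'   (dimensionless, >= 1), `L_sys`, `h`, `delta_p` (um), `D` (um^2 s^-1),
#'   `A`, `B` (uM), `F_mem` (pN um^-1), `eta` (uM^-1 um^-3) and `kBT` (pN um).
#' @examples
#' p <- actin_parameters()
#' p$r_cap
#' p_no_tm <- actin_parameters(r_tm = 0)
#' @export
actin_parameters <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  p <- .param_defaults()
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, names(p))
    if (length(unknown)) {
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if ("eta" %in% nm && !isTRUE(all.equal(overrides$eta, ETA_UM3_PER_UM))) {
      stop("'eta' is a fixed unit conversion constant and cannot be overridden",
           call. = FALSE)
    }
    p[nm] <- lapply(overrides[nm], function(v) {
      if (is.numeric(v)) as.numeric(v) else v
    })
  }
  validate_parameters(p)
  structure(p, class = "actin_parameters")
}

#' Valid parameter field names
#' @return Character vector of the field names accepted by
#'   [actin_parameters()] and configuration files.
#' @export
actin_parameter_names <- function() names(.param_defaults())

validate_parameters <- function(p) {
  for (nm in names(.param_defaults())) {
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
    lo_ok <- if (nm %in% .zero_ok) v >= 0 else v > 0
    if (!lo_ok) {
      stop("parameter '", nm, "' must be ",
           if (nm %in% .zero_ok) "non-negative" else "strictly positive",
           " (got ", v, ")", call. = FALSE)
    }
  }
  if (p$s_ac < 1) stop("'s_ac' must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.actin_parameters <- function(x, ...) {
  cat("Treadmilling-network model parameters\n")
  df <- data.frame(value = unlist(x), row.names = names(x))
  print(df)
  invisible(x)
}

#' Load model parameters from a configuration file
#'
#' Reads a flat key-value configuration document (YAML or JSON; keys equal
#' the field names of [actin_parameters()]) and overlays it on the default
#' parameter set.  With `config = NULL` the defaults are returned.
#'
#' @param config path to a YAML/JSON file, a named list of overrides, or
#'   `NULL` for the defaults.
#' @return A validated `actin_parameters` object.
#' @examples
#' load_parameters(NULL)$D
#' load_parameters(list(r_tm = 0))$r_tm
#' @export
load_parameters <- function(config = NULL) {
  if (is.null(config)) return(actin_parameters())
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("configuration file not found: ", config, call. = FALSE)
    }
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
    } else {
      yaml::yaml.load(txt)
    }
  }
  if (!is.list(config)) {
    stop("config must be a file path, a named list, or NULL", call. = FALSE)
  }
  do.call(actin_parameters, config)
}

#' Serialize model parameters
#'
#' Writes the parameter set as a flat JSON document that [load_parameters()]
#' reads back bit-for-bit (full double precision).
#'
#' @param p an `actin_parameters` object.
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "actin_parameters"))
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load per unit filament at the leading edge
#'
#' The membrane resistance `F_mem` (pN per um of edge length) is shared by
#' the growing plus-ends abutting the membrane.  With plus-end density `B`
#' (uM) occupying a `delta_p`-deep zone of height `h`, the load per filament
#' is `f = F_mem / (B * h * delta_p * eta)`.
#'
#' @param B plus-end concentration at the leading edge, uM.
#' @param p an `actin_parameters` object.
#' @return Force per filament in pN (about 1 pN at the reference values).
#' @examples
#' filament_force(440, actin_parameters())
#' @export
filament_force <- function(B, p) {
  stopifnot(is.numeric(B), all(B > 0))
  p$F_mem / (B * p$h * p$delta_p * p$eta)
}

#' Numerical controls for the steady-state solver
#'
#' @param dx spatial step, um.  0.02 resolves the confined reference system;
#'   unconfined runs use coarser grids but never above 0.1.
#' @param dt temporal step of the kinetics grids, s.
#' @param dtau capped-time integration step, s; must be an integer multiple
#'   of `dt` (defaults to `dt`).  Coarser values speed up unconfined scans.
#' @param c0_tolerance fixed-point stopping tolerance on the leading-edge
#'   G-actin concentration, uM (50 nM default).
#' @param c0_initial starting guess for `c(0)`, uM.
#' @param damping relaxation factor in (0, 1] for the fixed-point update.
#' @param t_uc_max truncation horizon for uncapped times, s; `NULL` resolves
#'   to `15 / r_cap` at solve time (survival weight exp(-15), keeping the
#'   truncation bias of rear-field length averages below 1%).
#' @param tau_c_max cap on the capped-time horizon, s; `NULL` means adaptive:
#'   groups are integrated until the surviving fraction of the oldest group
#'   falls below `survival_cutoff` (or their plus-ends leave the box).
#' @param survival_cutoff relative surviving-concentration cutoff used by the
#'   adaptive capped-time truncation.
#' @param max_iterations fixed-point iteration budget.
#' @param length_threshold F-actin concentration, uM, below which the network
#'   is considered ended (network-length metric).
#' @return An object of class `numerical_controls`.
#' @export
numerical_controls <- function(dx = 0.02, dt = 0.01, dtau = dt,
                               c0_tolerance = 0.05, c0_initial = 10,
                               damping = 0.5, t_uc_max = NULL,
                               tau_c_max = NULL, survival_cutoff = 1e-4,
                               max_iterations = 200, length_threshold = 5) {
  stopifnot(dx > 0, dt > 0, dtau > 0, c0_tolerance > 0, c0_initial > 0,
            damping > 0, damping <= 1, survival_cutoff > 0,
            max_iterations >= 1, length_threshold > 0)
  m <- dtau / dt
  if (abs(m - round(m)) > 1e-8) {
    stop("'dtau' must be an integer multiple of 'dt'", call. = FALSE)
  }
  if (!is.null(t_uc_max)) stopifnot(t_uc_max > 0)
  if (!is.null(tau_c_max)) stopifnot(tau_c_max > 0)
  structure(list(dx = dx, dt = dt, dtau = dtau,
                 c0_tolerance = c0_tolerance, c0_initial = c0_initial,
                 damping = damping, t_uc_max = t_uc_max,
                 tau_c_max = tau_c_max, survival_cutoff = survival_cutoff,
                 max_iterations = max_iterations,
                 length_threshold = length_threshold),
            class = "numerical_controls")
}

#' @export
print.numerical_controls <- function(x, ...) {
  cat("Numerical controls\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm,
                if (is.null(x[[nm]])) "adaptive" else format(x[[nm]])))
  }
  invisible(x)
}

# Resolved uncapped-time horizon.  The default 15 / r_cap (survival weight
# exp(-15) ~ 3e-7) keeps the truncation bias of length-weighted fields in
# the low-density rear of the network below 1%; a 10 / r_cap horizon is
# noticeably too short there because the few filaments reaching the rear
# are drawn from the far tail of the uncapped-time distribution.
resolve_t_uc_max <- function(controls, p) {
  if (!is.null(controls$t_uc_max)) controls$t_uc_max else 15 / p$r_cap
}
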