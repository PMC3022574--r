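# Structured output: CSV tables with a '#'-prefixed JSON metadata header
# carrying the full parameter echo, and the command-line entry point.

meta_header <- function(p, extra = list()) {
  meta <- c(list(package = "actintread",
                 version = as.character(utils::packageVersion("actintread")),
                 parameters = unclass(p)), extra)
  paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
}

#' Write spatial profiles as CSV
#'
#' Columns `x, F, F_uc, F_c, M, J_d, c, L_mean, F_ac, F_tm`; the first line
#' is a `#`-prefixed JSON header echoing the parameter set (and convergence
#' report when a full solution is given).
#'
#' @param sol a `treadmill_solution` or `spatial_profiles` object.
#' @param path output path.
#' @param p parameters to echo (taken from the solution when available).
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(sol, path, p = NULL) {
  extra <- list()
  if (inherits(sol, "treadmill_solution")) {
    p <- sol$params
    extra <- list(mode = sol$mode,
                  convergence = sol$convergence[c("converged", "iterations",
                                                  "tolerance")],
                  c0 = sol$edge$c0, V_um_per_min = 60 * sol$edge$V)
    sol <- sol$profiles
  }
  stopifnot(!is.null(p))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(p, extra), con)
  utils::write.csv(as.data.frame(sol), con, row.names = FALSE)
  invisible(path)
}

#' Read a profiles CSV written by [write_profiles_csv()]
#'
#' @param path input path.
#' @return A data frame; the parsed JSON header is attached as attribute
#'   `metadata`.
#' @export
read_profiles_csv <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1L]))
  df <- utils::read.csv(text = lines[-1L])
  attr(df, "metadata") <- hdr
  df
}

#' Command-line entry point
#'
#' Thin dispatcher for shell use (`solve`, `scan`, `validate`), writing CSV
#' tables and JSON reports to an output directory.  See the repository's
#' `exec/actintread` script.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status, invisibly (0 on success, 2 on
#'   non-convergence or validation failure).
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    cat("usage: actintread <solve|scan|validate> [options]\n",
        "  solve    --config FILE --mode confined|unconfined --out DIR\n",
        "  scan     diffusion|capping-cofilin|regulators [--D v1,v2,...]",
        " --out DIR\n",
        "  validate --out DIR   (oracle agreement report)\n", sep = "")
    return(invisible(1L))
  }
  sub <- argv[1L]; rest <- argv[-1L]
  opt <- parse_cli_options(rest)
  out_dir <- opt$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- load_parameters(opt$config)
  status <- tryCatch(switch(
    sub,
    solve = cli_solve(p, opt, out_dir),
    scan = cli_scan(p, opt, out_dir),
    validate = cli_validate(p, opt, out_dir),
    { message("unknown subcommand: ", sub); 1L }
  ), error = function(e) {
    jsonlite::write_json(list(error = conditionMessage(e)),
                         file.path(out_dir, "error.json"),
                         auto_unbox = TRUE)
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

parse_cli_options <- function(rest) {
  opt <- list(positional = character(0))
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      opt[[key]] <- if (i + 1L <= length(rest)) rest[i + 1L] else ""
      i <- i + 2L
    } else {
      opt$positional <- c(opt$positional, a)
      i <- i + 1L
    }
  }
  opt
}

cli_solve <- function(p, opt, out_dir) {
  mode <- opt$mode %||% "confined"
  dx <- as.numeric(opt$dx %||% if (mode == "confined") 0.02 else 0.1)
  dtau <- as.numeric(opt$dtau %||% if (mode == "confined") 0.01 else 0.1)
  controls <- numerical_controls(dx = dx, dtau = dtau)
  sol <- solve_steady_state(p, controls, mode = mode)
  write_profiles_csv(sol, file.path(out_dir, "profiles.csv"))
  jsonlite::write_json(
    c(sol$convergence[c("converged", "iterations", "tolerance")],
      list(residuals = sol$convergence$residuals, c0 = sol$edge$c0,
           V_um_per_min = 60 * sol$edge$V,
           L_net = network_length(sol))),
    file.path(out_dir, "convergence.json"), auto_unbox = TRUE, digits = NA)
  0L
}

cli_scan <- function(p, opt, out_dir) {
  what <- opt$positional[1L] %||% "diffusion"
  controls <- numerical_controls(dx = as.numeric(opt$dx %||% 0.1),
                                 dtau = as.numeric(opt$dtau %||% 0.1))
  if (what == "diffusion") {
    D <- if (!is.null(opt$D)) as.numeric(strsplit(opt$D, ",")[[1L]]) else
      c(1, 2, 3, 5, 7, 10)
    sc <- diffusion_scan(p, controls, D_values = D, quiet = TRUE)
    utils::write.csv(sc$table, file.path(out_dir, "scan.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(L_net = unclass(sc$fit_L),
                              V = unclass(sc$fit_V)),
                         file.path(out_dir, "powerlaw.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (what == "capping-cofilin") {
    rc <- if (!is.null(opt$r_cap)) as.numeric(strsplit(opt$r_cap, ",")[[1L]])
      else c(0.5, 1, 2, 3.5, 5)
    ra <- if (!is.null(opt$r_ac)) as.numeric(strsplit(opt$r_ac, ",")[[1L]])
      else c(0.1, 0.5, 1)
    sc <- capping_cofilin_scan(p, controls, rc, ra,
                               deactivation = opt$deactivation %||% "on")
    utils::write.csv(as.data.frame(sc), file.path(out_dir, "scan.csv"),
                     row.names = FALSE)
  } else if (what == "regulators") {
    controls <- numerical_controls(dx = as.numeric(opt$dx %||% 0.05),
                                   dtau = as.numeric(opt$dtau %||% 0.02))
    rep_ <- regulator_effect_report(p, controls,
                                    r_ac_values = c(0.1, 0.5, 1),
                                    r_tm_values = c(0, 0.2, 0.5))
    utils::write.csv(rep_, file.path(out_dir, "scan.csv"), row.names = FALSE)
  } else {
    message("unknown scan: ", what); return(1L)
  }
  0L
}

cli_validate <- function(p, opt, out_dir) {
  controls <- numerical_controls(dx = as.numeric(opt$dx %||% 0.02),
                                 dtau = as.numeric(opt$dtau %||% 0.01))
  edge <- edge_state(as.numeric(opt$c0 %||% 15), p)
  r_const <- as.numeric(opt$r_const %||% (p$s_ac * p$k_off_minus))
  L_box <- as.numeric(opt$L_box %||% 12)
  traj <- constant_rate_trajectory(r_const, t_max = 10 / p$r_cap +
                                     1.1 * L_box / edge$V, dt = controls$dt)
  prof <- network_profiles(edge, traj, p, controls, L_box = L_box)
  cf <- constant_rate_solution(p, edge, r_const, prof$x)
  dev <- c(compare_profiles(prof, cf, fields = c("F", "L_mean"),
                            F_floor = controls$length_threshold),
           compare_profiles(prof, cf, fields = c("M", "J_d"),
                            F_floor = controls$length_threshold,
                            x_min = 2 * controls$dx))
  ok <- all(dev < 0.05)
  jsonlite::write_json(list(max_relative_deviation = as.list(dev),
                            pass = ok),
                       file.path(out_dir, "validate.json"),
                       auto_unbox = TRUE, digits = NA)
  if (ok) 0L else 2L
}
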