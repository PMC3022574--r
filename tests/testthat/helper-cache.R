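# Shared, lazily computed solutions.  The heavier solves are reused across
# test files so that the whole suite performs each expensive computation
# exactly once.

.solution_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .solution_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .solution_cache)
  }
  get(name, envir = .solution_cache, inherits = FALSE)
}

# Reference confined solution at the full production resolution
# (dx = 0.02 um, dt = dtau = 0.01 s).
baseline_solution <- function() {
  cached("baseline", solve_steady_state(actin_parameters(),
                                        numerical_controls(),
                                        mode = "confined"))
}

# Coarse confined solution used by structural/invariant tests where the
# full resolution is unnecessary.
coarse_solution <- function() {
  cached("coarse", solve_steady_state(
    actin_parameters(),
    numerical_controls(dx = 0.05, dt = 0.02, dtau = 0.04),
    mode = "confined"))
}

# Edge state + aged trajectory used by fixed-edge profile tests (no
# fixed-point solve involved).
fixed_edge <- function() {
  cached("fixed_edge", {
    p <- actin_parameters()
    edge <- edge_state(15, p)
    traj <- subunit_states(p, t_max = 15 / p$r_cap + 1.1 * 10 / edge$V,
                           dt = 0.01)
    list(p = p, edge = edge, traj = traj)
  })
}

# Unconfined tropomyosin-free diffusion scan at the scan resolution
# (dx = 0.1 um, dtau = 0.1 s).
unconfined_scan <- function() {
  cached("dscan", diffusion_scan(actin_parameters(),
                                 numerical_controls(dx = 0.1, dtau = 0.1)))
}
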