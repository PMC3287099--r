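# Shared fixtures. All fixtures are generated in code; the solved-cohort
# cache is memoized per test file so several test_that() blocks can share
# one round of PDE solves.

small_geometry <- function(n = 40L) grid_geometry(extent_mm = 6, n = n)

# A field_state built by hand (bypasses the Gaussian initial condition),
# for solver tests that need full control of c.
manual_state <- function(K, c) {
  structure(list(K = K, c = c, t = 0, steps = 0L), class = "field_state")
}

# Run the explicit scheme to its fixed point (no stationarity monitor).
iterate_steps <- function(state, domain, params, n_steps) {
  sc <- oxymap:::solver_scales(params, domain$geometry)
  for (s in seq_len(n_steps)) state <- step_fields(state, domain, params, sc)
  state
}

.cohort_cache <- new.env(parent = emptyenv())

# Cohorts of 8 synthetic tumors on the default 100x100 grid, solved to
# stationary hypoxia. Replicate r is fully determined by seed 100 + r.
solved_cohorts <- function(n_cohorts) {
  key <- as.character(n_cohorts)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- lapply(seq_len(n_cohorts), function(r) {
      domains <- generate_cohort(8, synth_params(), seed = 100 + r)
      suppressWarnings(solve_cohort(domains))
    })
  }
  .cohort_cache[[key]]
}

# Per-tumor electrode HP5 estimates for one cohort and strategy.
cohort_electrode_hp5 <- function(cohort, strategy, n_tracks = 6,
                                 seed = 1) {
  vapply(seq_along(cohort), function(ti) {
    plan <- make_plan(strategy, n_tracks, cohort[[ti]]$domain,
                      seed = oxymap:::derive_seed(seed, strategy, ti))
    r <- suppressWarnings(
      sample_readings(plan, cohort[[ti]]$field$K,
                      cohort[[ti]]$domain$geometry,
                      tumor_mask = cohort[[ti]]$domain$tumor_mask))
    hp_from_readings(r, max(cohort[[ti]]$field$K), 5)
  }, 0)
}

cohort_area_hp5 <- function(cohort) {
  vapply(cohort, function(x)
    hypoxic_area_fraction(x$field$K, x$domain$tumor_mask, 5), 0)
}
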