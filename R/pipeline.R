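#' Solve every tumor of a cohort to stationary hypoxia
#'
#' @param domains List of [vascular_domain()] objects.
#' @param params A [solver_params()].
#' @param ... Passed to [solve_to_stationary_hypoxia()].
#' @return An object of class `solved_cohort`: a list of
#'   `list(domain, field)` pairs.
#' @export
solve_cohort <- function(domains, params = solver_params(), ...) {
  out <- lapply(domains, function(d)
    list(domain = d, field = solve_to_stationary_hypoxia(d, params, ...)))
  class(out) <- "solved_cohort"
  out
}

#' Match the geometric diffusion limit to a simulated hypoxia threshold
#'
#' The synthetic reference hypoxia mask marks tissue farther than a
#' diffusion-limit distance from the nearest perfused vessel. For the
#' reference and the transport model to describe the same hypoxic
#' compartment, the distance limit must correspond to the model's
#' relative threshold. This calibration equates areas on one solved
#' domain: it returns the distance quantile at which the fraction of
#' tumor tissue beyond the limit equals the simulated hypoxic area
#' fraction at `pct`. Calibrate on a held-out domain, then apply the
#' returned limit when generating reference masks for validation cohorts.
#'
#' @param domain A [vascular_domain()] with at least one perfused vessel.
#' @param field A solved `field_state` for that domain.
#' @param pct Relative hypoxia threshold (percent of field maximum).
#' @return Matched diffusion limit in mm.
#' @export
match_diffusion_limit <- function(domain, field, pct = 5) {
  hp <- hypoxic_area_fraction(field$K, domain$tumor_mask, pct)
  d <- perfused_distance_map(domain)[domain$tumor_mask]
  as.numeric(stats::quantile(d, 1 - hp, names = FALSE, type = 7))
}

#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run: cohort synthesis (or input
#' directories), solver settings, hypoxia thresholds, electrode
#' strategies, variance settings, dose grid and the master seed from
#' which all module seeds are derived. Serializable to JSON via
#' [jsonlite::write_json()] of `unclass(config)`.
#'
#' @param n_tumors Cohort size.
#' @param geometry A [grid_geometry()].
#' @param synth A [synth_params()] template for synthetic cohorts, or
#'   `NULL` when `input_dirs` is given.
#' @param input_dirs Optional character vector of directories readable by
#'   [read_domain()]; overrides synthesis.
#' @param solver A [solver_params()].
#' @param thresholds Relative hypoxia thresholds (percent).
#' @param strategies Electrode strategies to evaluate (may be empty).
#' @param n_tracks Track count for per-tumor electrode estimates.
#' @param max_tracks,replicates Settings for [variance_vs_tracks()].
#' @param doses Dose grid (Gy) for [scenario_curves()].
#' @param seed Master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_tumors = 8L,
                              geometry = grid_geometry(),
                              synth = synth_params(),
                              input_dirs = NULL,
                              solver = solver_params(),
                              thresholds = c(2.5, 5, 10),
                              strategies = c("uniform", "random",
                                             "half_radial", "full_radial"),
                              n_tracks = 6L,
                              max_tracks = 8L,
                              replicates = 5L,
                              doses = seq(0, 10, by = 0.5),
                              seed = 1L) {
  structure(
    list(n_tumors = as.integer(n_tumors), geometry = geometry,
         synth = synth, input_dirs = input_dirs, solver = solver,
         thresholds = thresholds, strategies = strategies,
         n_tracks = as.integer(n_tracks),
         max_tracks = as.integer(max_tracks),
         replicates = as.integer(replicates),
         doses = doses, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

round_signif <- function(df, digits = 10) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

#' Run a full hypoxia-mapping experiment
#'
#' End-to-end driver: synthesize (or load) a cohort of tumor
#' cross-sections, solve each to a stationary oxygen distribution,
#' quantify hypoxia by the area and electrode methods, decompose
#' measurement variance per strategy, and compute radiation-response
#' curves for a representative tumor. All randomness derives from the
#' master seed; an identical configuration reproduces the bundle exactly
#' (numeric CSV columns are rounded to 10 significant digits before
#' writing).
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, CSV tables and a JSON
#'   manifest are written into it.
#' @return A list with `reports` (per-tumor [hypoxia_report()]s),
#'   `hp_table` (long data frame of per-tumor HP estimates),
#'   `variance_tracks` (per-strategy [variance_vs_tracks()] tables),
#'   `variance_methods` (per-strategy between-methods percentages),
#'   `radiation` (scenario curves), `trace` (convergence traces) and
#'   `cohort` (the solved cohort).
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  domains <- if (!is.null(config$input_dirs)) {
    lapply(config$input_dirs, read_domain)
  } else {
    generate_cohort(config$n_tumors, config$synth, config$geometry,
                    seed = derive_seed(config$seed, "synth"))
  }
  cohort <- solve_cohort(domains, config$solver)

  hp_rows <- list()
  reports <- vector("list", length(cohort))
  for (ti in seq_along(cohort)) {
    domain <- cohort[[ti]]$domain
    field <- cohort[[ti]]$field
    reports[[ti]] <- hypoxia_report(field, domain, config$thresholds)
    hp_rows[[length(hp_rows) + 1L]] <- data.frame(
      tumor = ti, method = "area", strategy = NA_character_,
      threshold = config$thresholds,
      hp = unname(reports[[ti]]$hp_area))
    for (strat in config$strategies) {
      plan <- make_plan(strat, config$n_tracks, domain,
                        seed = derive_seed(config$seed, "plan", strat, ti))
      hp_e <- hp_from_readings(
        sample_readings(plan, field$K, domain$geometry,
                        tumor_mask = domain$tumor_mask),
        max(field$K), config$thresholds)
      hp_rows[[length(hp_rows) + 1L]] <- data.frame(
        tumor = ti, method = "electrode", strategy = strat,
        threshold = config$thresholds, hp = unname(hp_e))
    }
  }
  hp_table <- do.call(rbind, hp_rows)

  variance_tracks <- NULL
  variance_methods <- NULL
  if (length(config$strategies) > 0) {
    variance_tracks <- do.call(rbind, lapply(config$strategies, function(s)
      variance_vs_tracks(cohort, s, max_tracks = config$max_tracks,
                         replicates = if (s == "random")
                           config$replicates else 1L,
                         seed = derive_seed(config$seed, "variance", s))))
    key <- config$thresholds[which.min(abs(config$thresholds - 5))]
    area <- hp_table$hp[hp_table$method == "area" &
                          hp_table$threshold == key]
    variance_methods <- data.frame(
      strategy = config$strategies,
      pct_total_methods = vapply(config$strategies, function(s) {
        elec <- hp_table$hp[hp_table$method == "electrode" &
                              hp_table$strategy == s &
                              hp_table$threshold == key]
        between_methods(area, elec)$pct_total_methods
      }, 0))
  }

  radiation <- scenario_curves(cohort[[1L]]$field$K,
                               cohort[[1L]]$domain$tumor_mask,
                               doses = config$doses)

  trace <- do.call(rbind, lapply(seq_along(cohort), function(ti)
    cbind(tumor = ti, cohort[[ti]]$field$trace)))

  bundle <- list(reports = reports, hp_table = hp_table,
                 variance_tracks = variance_tracks,
                 variance_methods = variance_methods,
                 radiation = radiation, trace = trace, cohort = cohort)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(round_signif(hp_table),
                     file.path(out_dir, "hypoxia_estimates.csv"),
                     row.names = FALSE)
    if (!is.null(variance_tracks))
      utils::write.csv(round_signif(variance_tracks),
                       file.path(out_dir, "variance_tracks.csv"),
                       row.names = FALSE)
    if (!is.null(variance_methods))
      utils::write.csv(round_signif(variance_methods),
                       file.path(out_dir, "variance_methods.csv"),
                       row.names = FALSE)
    utils::write.csv(round_signif(radiation),
                     file.path(out_dir, "radiation_survival.csv"),
                     row.names = FALSE)
    utils::write.csv(round_signif(trace),
                     file.path(out_dir, "convergence_trace.csv"),
                     row.names = FALSE)
    manifest <- list(
      seed = config$seed,
      n_tumors = length(cohort),
      geometry = unclass(config$geometry),
      thresholds = config$thresholds,
      strategies = config$strategies,
      package_version = as.character(utils::packageVersion("oxymap")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
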