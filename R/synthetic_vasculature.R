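#' Parameters for synthetic vascular-map generation
#'
#' Controls the seeded generator that emulates binarized histology of a
#' tumor cross-section: sparse single-cell vessel cross-sections placed
#' inside a blob- or ellipse-shaped tumor mask, a randomly chosen perfused
#' subset, and a geometric reference hypoxia mask marking tumor tissue
#' beyond a diffusion-limit distance from the nearest perfused vessel
#' (a proxy for nitroimidazole marker binding).
#'
#' @param n_vessels Number of vessel cross-sections to place (>= 1).
#' @param perfused_fraction Fraction of vessels carrying flow, in `[0, 1]`;
#'   `round(perfused_fraction * n_vessels)` vessels are flagged perfused.
#' @param clustering `"uniform"` scatters vessels uniformly over the tumor;
#'   `"lognormal-spacing"` places them sequentially with nearest-neighbour
#'   spacing drawn from a lognormal intervascular-distance distribution.
#' @param lognormal_mu,lognormal_sigma Log-scale location and scale of the
#'   intervascular distance (mm); defaults give a median spacing of
#'   0.25 mm, typical of xenograft capillary networks.
#' @param tumor_shape `"blob"` (ellipse with smooth radial perturbation)
#'   or `"ellipse"`.
#' @param diffusion_limit_mm Distance threshold (mm) beyond which tumor
#'   tissue is marked reference-hypoxic; default 0.15 mm, the order of the
#'   oxygen diffusion limit around a capillary.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_vessels = 40L,
                         perfused_fraction = 0.6,
                         clustering = c("uniform", "lognormal-spacing"),
                         lognormal_mu = log(0.25),
                         lognormal_sigma = 0.5,
                         tumor_shape = c("blob", "ellipse"),
                         diffusion_limit_mm = 0.15,
                         seed = 1L) {
  clustering <- match.arg(clustering)
  tumor_shape <- match.arg(tumor_shape)
  n_vessels <- as.integer(n_vessels)
  stopifnot(n_vessels >= 1L,
            perfused_fraction >= 0, perfused_fraction <= 1,
            diffusion_limit_mm > 0)
  structure(
    list(n_vessels = n_vessels, perfused_fraction = perfused_fraction,
         clustering = clustering, lognormal_mu = lognormal_mu,
         lognormal_sigma = lognormal_sigma, tumor_shape = tumor_shape,
         diffusion_limit_mm = diffusion_limit_mm, seed = as.integer(seed)),
    class = "synth_params"
  )
}

## Star-shaped tumor mask around the grid centre. The blob perturbs an
## ellipse radius with three low-order harmonics; amplitudes are bounded
## so the mask always covers at least a quarter of the grid and remains
## connected (star-shaped by construction).
make_tumor_mask <- function(shape, geometry) {
  n <- geometry$n
  ctr <- cell_centers(geometry)
  cx <- geometry$extent_mm / 2
  cy <- geometry$extent_mm / 2
  dx <- ctr$x - cx
  dy <- ctr$y - cy
  theta <- atan2(dy, dx)
  r0 <- 0.38 * geometry$extent_mm
  ecc <- 0.88  # semi-minor/semi-major ratio of the base ellipse
  base <- r0 * ecc / sqrt(ecc^2 * cos(theta)^2 + sin(theta)^2)
  if (shape == "blob") {
    amp <- stats::runif(3, 0, 0.12 / (1:3))
    phase <- stats::runif(3, 0, 2 * pi)
    pert <- amp[1] * cos(1 * theta + phase[1]) +
      amp[2] * cos(2 * theta + phase[2]) +
      amp[3] * cos(3 * theta + phase[3])
    base <- base * (1 + pert)
  }
  sqrt(dx^2 + dy^2) <= base
}

#' Euclidean distance to the nearest perfused vessel
#'
#' Computes, for every grid cell centre, the distance in mm to the nearest
#' perfused-vessel cell centre. With no perfused vessels the distance to
#' the empty set is `Inf`, so every tumor cell is reference-hypoxic.
#'
#' @param domain A [vascular_domain()].
#' @return An `n x n` numeric matrix of distances (mm).
#' @export
perfused_distance_map <- function(domain) {
  geometry <- domain$geometry
  ctr <- cell_centers(geometry)
  idx <- which(domain$perfused_mask)
  d <- matrix(Inf, geometry$n, geometry$n)
  for (k in idx) {
    d <- pmin(d, sqrt((ctr$x - ctr$x[k])^2 + (ctr$y - ctr$y[k])^2))
  }
  d
}

#' Generate one synthetic vascular domain
#'
#' Builds a [vascular_domain()] from [synth_params()]: a connected tumor
#' mask covering at least 25% of the grid, single-cell vessel
#' cross-sections inside it, a simple random perfused subset, and a
#' distance-based reference hypoxia mask.
#'
#' @param params A [synth_params()].
#' @param geometry A [grid_geometry()].
#' @return A [vascular_domain()] with `hypoxia_reference_mask` set.
#' @export
generate_domain <- function(params = synth_params(),
                            geometry = grid_geometry()) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    tumor <- make_tumor_mask(params$tumor_shape, geometry)
    tumor_cells <- which(tumor)
    if (params$n_vessels > length(tumor_cells))
      stop("capacity error: ", params$n_vessels,
           " vessels exceed the ", length(tumor_cells), " tumor cells")
    vessel_cells <- switch(params$clustering,
      uniform = sample(tumor_cells, params$n_vessels),
      `lognormal-spacing` = place_lognormal_vessels(params, geometry, tumor)
    )
    vessel <- matrix(FALSE, geometry$n, geometry$n)
    vessel[vessel_cells] <- TRUE
    n_perf <- round(params$perfused_fraction * params$n_vessels)
    perf_cells <- if (n_perf > 0)
      sample(vessel_cells, n_perf) else integer(0)
    perfusion <- matrix(FALSE, geometry$n, geometry$n)
    perfusion[perf_cells] <- TRUE
    domain <- vascular_domain(vessel, perfusion, tumor, geometry)
    d <- perfused_distance_map(domain)
    domain$hypoxia_reference_mask <- tumor & d > params$diffusion_limit_mm
    domain
  })
}

## Sequential placement with lognormal nearest-neighbour spacing: each new
## vessel is put at a lognormal distance, uniform angle, from a randomly
## chosen existing vessel; off-tumor or occupied proposals are redrawn.
place_lognormal_vessels <- function(params, geometry, tumor) {
  n <- geometry$n
  s <- geometry$spacing_mm
  tumor_cells <- which(tumor)
  cells <- sample(tumor_cells, 1L)
  max_tries <- 200L * params$n_vessels
  tries <- 0L
  while (length(cells) < params$n_vessels && tries < max_tries) {
    tries <- tries + 1L
    anchor <- cells[sample.int(length(cells), 1L)]
    ai <- (anchor - 1L) %% n + 1L
    aj <- (anchor - 1L) %/% n + 1L
    r <- stats::rlnorm(1, params$lognormal_mu, params$lognormal_sigma)
    th <- stats::runif(1, 0, 2 * pi)
    x <- (aj - 0.5) * s + r * cos(th)
    y <- (ai - 0.5) * s + r * sin(th)
    cell <- position_to_cell(x, y, geometry)
    if (is.na(cell[1L])) next
    lin <- (cell[1L, "j"] - 1L) * n + cell[1L, "i"]
    if (!tumor[lin] || lin %in% cells) next
    cells <- c(cells, lin)
  }
  if (length(cells) < params$n_vessels)
    stop("capacity error: could not place ", params$n_vessels,
         " vessels with the requested spacing distribution")
  cells
}

#' Generate a cohort of synthetic tumor cross-sections
#'
#' Produces independent seeded domains with varying vascular density, so
#' that a cohort carries genuine between-tumor variation in oxygenation.
#' Either supply one [synth_params()] per tumor, or a single template
#' whose `n_vessels` is swept across `n_vessels_range`.
#'
#' @param n_tumors Cohort size (>= 2).
#' @param params_list A single [synth_params()] template, or a list of one
#'   per tumor.
#' @param geometry A [grid_geometry()].
#' @param seed Master seed from which per-tumor seeds are derived (used
#'   only with a single template).
#' @param n_vessels_range Range of vessel counts swept linearly across the
#'   cohort when a single template is given.
#' @return A list of [vascular_domain()] objects.
#' @export
generate_cohort <- function(n_tumors = 8L,
                            params_list = synth_params(),
                            geometry = grid_geometry(),
                            seed = 1L,
                            n_vessels_range = c(24L, 80L)) {
  n_tumors <- as.integer(n_tumors)
  stopifnot(n_tumors >= 2L)
  if (inherits(params_list, "synth_params")) {
    counts <- round(seq(n_vessels_range[1L], n_vessels_range[2L],
                        length.out = n_tumors))
    params_list <- lapply(seq_len(n_tumors), function(i) {
      p <- params_list
      p$n_vessels <- as.integer(counts[i])
      p$seed <- derive_seed(seed, "synthetic_vasculature", i)
      p
    })
  }
  stopifnot(length(params_list) == n_tumors)
  lapply(params_list, generate_domain, geometry = geometry)
}
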