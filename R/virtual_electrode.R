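## Tumor-mask geometry helpers used to lay out electrode tracks.

tumor_centroid <- function(domain) {
  ctr <- cell_centers(domain$geometry)
  c(x = mean(ctr$x[domain$tumor_mask]), y = mean(ctr$y[domain$tumor_mask]))
}

tumor_bbox <- function(domain) {
  idx <- which(domain$tumor_mask, arr.ind = TRUE)
  s <- domain$geometry$spacing_mm
  list(x_min = (min(idx[, 2]) - 1) * s, x_max = max(idx[, 2]) * s,
       y_min = (min(idx[, 1]) - 1) * s, y_max = max(idx[, 1]) * s)
}

## Boundary cells of the tumor mask: tumor cells with a 4-neighbour
## outside the mask (grid edge counts as outside).
tumor_boundary_cells <- function(domain) {
  m <- domain$tumor_mask
  n <- nrow(m)
  pad <- matrix(FALSE, n + 2L, n + 2L)
  pad[2:(n + 1L), 2:(n + 1L)] <- m
  inner <- pad[1:n, 2:(n + 1L)] & pad[3:(n + 2L), 2:(n + 1L)] &
    pad[2:(n + 1L), 1:n] & pad[2:(n + 1L), 3:(n + 2L)]
  which(m & !inner)
}

## Walk outward from the centroid along a direction with y measured
## upwards (math convention; rows increase downwards) and return the last
## point still inside the tumor mask, in mm.
boundary_exit_point <- function(domain, angle_deg) {
  g <- domain$geometry
  ctr <- tumor_centroid(domain)
  step <- g$spacing_mm / 2
  dir <- c(cos(angle_deg * pi / 180), -sin(angle_deg * pi / 180))
  pos <- c(ctr[["x"]], ctr[["y"]])
  last_inside <- pos
  max_iter <- ceiling(2 * g$extent_mm / step)
  for (k in seq_len(max_iter)) {
    cand <- pos + step * dir
    cell <- position_to_cell(cand[1], cand[2], g)
    if (is.na(cell[1L]) || !domain$tumor_mask[cell[1L, "i"], cell[1L, "j"]])
      break
    pos <- cand
    last_inside <- cand
  }
  last_inside
}

#' Build a needle-electrode sampling plan
#'
#' Lays out linear measurement tracks over a tumor cross-section under
#' one of four placement strategies:
#' \describe{
#'   \item{uniform}{parallel vertical tracks at equally spaced
#'     x-positions across the tumor bounding box (positions `w/(k+1)`,
#'     `2w/(k+1)`, ... from the left edge), entering from the top.}
#'   \item{random}{entry points drawn uniformly on the tumor boundary,
#'     each aimed at a uniformly drawn interior tumor point.}
#'   \item{half_radial}{entry angles evenly spaced over a limited arc
#'     (default 60--120 degrees from the +x axis, i.e. the 10-o'clock to
#'     2-o'clock positions, tumor accessible from one side only), each
#'     needle advancing from the tumor surface to the tumor centroid.}
#'   \item{full_radial}{entry angles evenly spaced over the full circle,
#'     each needle advancing from the surface to the centroid.}
#' }
#' Each track holds `n_readings` measurement positions `step_mm` apart;
#' positions falling outside the grid are dropped at sampling time.
#' Radial needles stop at the centroid (the tip is not pushed out the
#' far side of the tumor), so a radial track carries fewer readings when
#' the surface-to-centroid distance is shorter than the nominal track
#' length; this confinement of radial sampling to the entry sector is
#' what makes a narrow-arc radial fan a small effective sampling area.
#'
#' @param strategy One of `"uniform"`, `"random"`, `"half_radial"`,
#'   `"full_radial"`.
#' @param n_tracks Number of tracks (>= 1).
#' @param domain A [vascular_domain()].
#' @param seed Integer seed (required for `"random"`).
#' @param step_mm Spacing between measurements along a track (default
#'   0.2 mm).
#' @param n_readings Measurements per track (default 25; conventional
#'   practice uses 20--30).
#' @param arc_deg Arc limits in degrees for `"half_radial"` (default
#'   `c(60, 120)`; use `c(0, 180)` for a 9-to-3-o'clock fan).
#' @return An object of class `sampling_plan` holding the track list.
#' @export
make_plan <- function(strategy = c("uniform", "random", "half_radial",
                                   "full_radial"),
                      n_tracks, domain, seed = NULL, step_mm = 0.2,
                      n_readings = 25L, arc_deg = c(60, 120)) {
  strategy <- match.arg(strategy)
  n_tracks <- as.integer(n_tracks)
  n_readings <- as.integer(n_readings)
  stopifnot(n_tracks >= 1L, step_mm > 0, n_readings >= 2L)
  g <- domain$geometry
  ctr <- tumor_centroid(domain)

  track <- function(entry, dir, max_len_mm = Inf) {
    len <- sqrt(sum(dir^2))
    if (len == 0) dir <- c(0, 1) else dir <- dir / len
    nr <- min(n_readings, floor(max_len_mm / step_mm) + 1L)
    list(entry = entry, direction = dir, step_mm = step_mm,
         n_readings = max(2L, as.integer(nr)))
  }

  radial_track <- function(angle_deg) {
    entry <- boundary_exit_point(domain, angle_deg)
    to_ctr <- c(ctr[["x"]], ctr[["y"]]) - entry
    track(entry, to_ctr, max_len_mm = sqrt(sum(to_ctr^2)))
  }

  tracks <- switch(strategy,
    uniform = {
      bb <- tumor_bbox(domain)
      w <- bb$x_max - bb$x_min
      xs <- bb$x_min + seq_len(n_tracks) * w / (n_tracks + 1)
      lapply(xs, function(x) track(c(x, bb$y_min), c(0, 1)))
    },
    random = {
      if (is.null(seed)) stop("random strategy requires a seed")
      with_seed(seed, {
        bcells <- tumor_boundary_cells(domain)
        if (n_tracks > length(bcells))
          stop("geometry error: ", n_tracks, " tracks cannot be kept ",
               "distinct at the grid resolution (only ", length(bcells),
               " boundary cells)")
        entries <- sample(bcells, n_tracks)  # without replacement
        tcells <- which(domain$tumor_mask)
        n <- g$n
        s <- g$spacing_mm
        lapply(seq_len(n_tracks), function(k) {
          b <- entries[k]
          p <- tcells[sample.int(length(tcells), 1L)]
          entry <- c(((b - 1L) %/% n + 0.5) * s, ((b - 1L) %% n + 0.5) * s)
          target <- c(((p - 1L) %/% n + 0.5) * s, ((p - 1L) %% n + 0.5) * s)
          dir <- target - entry
          if (all(dir == 0)) dir <- c(ctr[["x"]], ctr[["y"]]) - entry
          track(entry, dir)
        })
      })
    },
    half_radial = {
      angles <- if (n_tracks == 1L) mean(arc_deg) else
        seq(arc_deg[1L], arc_deg[2L], length.out = n_tracks)
      lapply(angles, radial_track)
    },
    full_radial = {
      angles <- 90 + 360 * (seq_len(n_tracks) - 1L) / n_tracks
      lapply(angles, radial_track)
    }
  )

  entry_cells <- vapply(tracks, function(tr) {
    cell <- position_to_cell(tr$entry[1], tr$entry[2], g)
    (cell[1L, "j"] - 1L) * g$n + cell[1L, "i"]
  }, 0L)
  if (anyDuplicated(entry_cells))
    stop("geometry error: ", n_tracks, " tracks cannot be kept distinct ",
         "at the grid resolution (coincident entry cells)")

  structure(list(strategy = strategy, tracks = tracks, seed = seed,
                 arc_deg = if (strategy == "half_radial") arc_deg),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> %s, %d tracks x %d readings (%g mm apart)\n",
              x$strategy, length(x$tracks), x$tracks[[1L]]$n_readings,
              x$tracks[[1L]]$step_mm))
  invisible(x)
}

#' Sample an oxygen field along electrode tracks
#'
#' Reads the oxygen concentration at each measurement position of a plan.
#' One grid cell (60 um at the default geometry) is the measurement
#' volume of the electrode tip, so a reading is the value of the cell
#' containing the position; positions outside the grid are dropped with
#' a warning. When a `tumor_mask` is supplied, positions falling in
#' non-tumor tissue are dropped silently -- the electrode protocol
#' measures tumor oxygenation, and counting extratumoral tissue would
#' bias the hypoxic fraction wherever a nominal track length overshoots
#' the tumor. Instrument noise is off by default; a Gaussian error with
#' standard deviation `noise_sd` (clamped at zero) can be added for
#' robustness studies.
#'
#' @param plan A [make_plan()] sampling plan.
#' @param K Oxygen field matrix.
#' @param geometry The [grid_geometry()] of the field.
#' @param tumor_mask Optional logical matrix; readings outside it are
#'   dropped.
#' @param noise_sd Standard deviation of optional additive Gaussian
#'   instrument noise (model units).
#' @param noise_seed Seed for the noise draw.
#' @return An object of class `reading_set`: a data frame with columns
#'   `track`, `x_mm`, `y_mm`, `value`.
#' @export
sample_readings <- function(plan, K, geometry, tumor_mask = NULL,
                            noise_sd = 0, noise_seed = NULL) {
  stopifnot(inherits(plan, "sampling_plan"))
  rows <- lapply(seq_along(plan$tracks), function(ti) {
    tr <- plan$tracks[[ti]]
    k <- seq_len(tr$n_readings) - 1L
    x <- tr$entry[1] + k * tr$step_mm * tr$direction[1]
    y <- tr$entry[2] + k * tr$step_mm * tr$direction[2]
    cells <- position_to_cell(x, y, geometry)
    keep <- !is.na(cells[, "i"])
    if (!all(keep))
      warning(sum(!keep), " reading position(s) on track ", ti,
              " fall outside the grid and were dropped")
    if (!is.null(tumor_mask)) {
      safe <- cbind(ifelse(keep, cells[, "i"], 1L),
                    ifelse(keep, cells[, "j"], 1L))
      keep <- keep & tumor_mask[safe]
    }
    data.frame(track = ti, x_mm = x[keep], y_mm = y[keep],
               value = K[cells[keep, , drop = FALSE]])
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("empty sample: no reading positions fall inside the grid")
  if (noise_sd > 0) {
    noise <- if (is.null(noise_seed)) stats::rnorm(nrow(out), 0, noise_sd)
    else with_seed(noise_seed, stats::rnorm(nrow(out), 0, noise_sd))
    out$value <- pmax(0, out$value + noise)
  }
  class(out) <- c("reading_set", "data.frame")
  out
}

#' Hypoxic fractions from pooled electrode readings
#'
#' Fraction of all readings, pooled over tracks, strictly below each
#' relative threshold: `pct`% of the field maximum `K_max`. Using the
#' same global reference maximum as the area method keeps the two
#' estimators directly comparable; pass `K_max = max(readings$value)` to
#' reference the readings themselves instead.
#'
#' @param readings A [sample_readings()] result.
#' @param K_max Reference maximum oxygen concentration (> 0).
#' @param thresholds Numeric vector of relative thresholds (percent).
#' @return Named numeric vector of fractions, keyed by threshold label.
#' @export
hp_from_readings <- function(readings, K_max, thresholds = c(2.5, 5, 10)) {
  stopifnot(K_max > 0)
  v <- readings$value
  out <- vapply(thresholds, function(p) mean(v < p / 100 * K_max), 0)
  names(out) <- vapply(thresholds, function(p)
    paste0("HP", format(p, trim = TRUE)), "")
  out
}
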