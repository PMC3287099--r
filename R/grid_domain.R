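#' Grid geometry of a square computational domain
#'
#' Describes the uniform square grid on which one tumor cross-section is
#' represented: a physical side length in millimetres divided into `n`
#' equal cells. The default configuration (6 mm, 100 points per side)
#' gives a cell spacing of 0.06 mm, about one capillary cross-section.
#'
#' Cells are addressed as matrix entries `[i, j]` with row `i` increasing
#' downwards and column `j` increasing to the right. The centre of cell
#' `[i, j]` sits at physical position `x = (j - 0.5) * spacing_mm`,
#' `y = (i - 0.5) * spacing_mm`; a continuous position maps to the cell
#' that contains it (`floor(position / spacing) + 1`).
#'
#' @param extent_mm Physical side length of the square domain (mm).
#' @param n Number of grid points per side (at least 8).
#' @return An object of class `grid_geometry` with fields `extent_mm`,
#'   `n` and the derived `spacing_mm`.
#' @examples
#' g <- grid_geometry()
#' g$spacing_mm  # 0.06
#' @export
grid_geometry <- function(extent_mm = 6, n = 100L) {
  stopifnot(is.numeric(extent_mm), length(extent_mm) == 1L, extent_mm > 0)
  n <- as.integer(n)
  if (is.na(n) || n < 8L) stop("grid must have at least 8 points per side")
  structure(
    list(extent_mm = as.numeric(extent_mm), n = n,
         spacing_mm = as.numeric(extent_mm) / n),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %g mm square, %d x %d cells (%g mm spacing)\n",
              x$extent_mm, x$n, x$n, x$spacing_mm))
  invisible(x)
}

## Map continuous mm positions to 1-based cell indices; NA outside the grid.
position_to_cell <- function(x_mm, y_mm, geometry) {
  j <- floor(x_mm / geometry$spacing_mm) + 1L
  i <- floor(y_mm / geometry$spacing_mm) + 1L
  outside <- i < 1L | i > geometry$n | j < 1L | j > geometry$n |
    !is.finite(x_mm) | !is.finite(y_mm)
  i[outside] <- NA_integer_
  j[outside] <- NA_integer_
  cbind(i = as.integer(i), j = as.integer(j))
}

## Physical centre coordinates (mm) of every cell, as n x n matrices.
cell_centers <- function(geometry) {
  s <- geometry$spacing_mm
  n <- geometry$n
  list(
    x = matrix(rep((seq_len(n) - 0.5) * s, each = n), n, n),
    y = matrix(rep((seq_len(n) - 0.5) * s, times = n), n, n)
  )
}

#' Construct a vascular domain from binary masks
#'
#' Bundles the co-registered binary masks of one tumor cross-section --
#' vessels, perfusion, total tumor area and (optionally) a reference
#' hypoxia mask -- with the grid geometry, and derives the perfused-vessel
#' map as the elementwise AND of the vessel and perfusion masks. Perfused
#' vessels are the oxygen sources of the transport model.
#'
#' @param vessel_mask,perfusion_mask,tumor_mask Logical `n x n` matrices.
#' @param geometry A [grid_geometry()].
#' @param hypoxia_reference_mask Optional logical `n x n` matrix marking
#'   hypoxic tissue as determined independently (e.g. nitroimidazole
#'   marker binding), used only for validation.
#' @return An object of class `vascular_domain` with the four input masks
#'   plus the derived `perfused_mask`.
#' @export
vascular_domain <- function(vessel_mask, perfusion_mask, tumor_mask,
                            geometry, hypoxia_reference_mask = NULL) {
  stopifnot(inherits(geometry, "grid_geometry"))
  n <- geometry$n
  as_mask <- function(m, name) {
    if (!is.matrix(m)) stop(name, " must be a matrix")
    if (!all(dim(m) == c(n, n)))
      stop(name, " must be ", n, " x ", n, ", got ",
           paste(dim(m), collapse = " x "))
    mode(m) <- "logical"
    m[is.na(m)] <- FALSE
    m
  }
  vessel_mask <- as_mask(vessel_mask, "vessel_mask")
  perfusion_mask <- as_mask(perfusion_mask, "perfusion_mask")
  tumor_mask <- as_mask(tumor_mask, "tumor_mask")
  if (!any(tumor_mask)) stop("empty domain: tumor mask has no positive cells")
  if (!is.null(hypoxia_reference_mask))
    hypoxia_reference_mask <- as_mask(hypoxia_reference_mask,
                                      "hypoxia_reference_mask")
  structure(
    list(geometry = geometry,
         vessel_mask = vessel_mask,
         perfusion_mask = perfusion_mask,
         tumor_mask = tumor_mask,
         perfused_mask = vessel_mask & perfusion_mask,
         hypoxia_reference_mask = hypoxia_reference_mask),
    class = "vascular_domain"
  )
}

#' @export
print.vascular_domain <- function(x, ...) {
  cat(sprintf(paste0(
    "<vascular_domain> %d x %d grid (%g mm)\n",
    "  tumor cells:    %d\n  vessel cells:   %d\n  perfused cells: %d%s\n"),
    x$geometry$n, x$geometry$n, x$geometry$extent_mm,
    sum(x$tumor_mask), sum(x$vessel_mask), sum(x$perfused_mask),
    if (is.null(x$hypoxia_reference_mask)) ""
    else sprintf("\n  reference hypoxic cells: %d",
                 sum(x$hypoxia_reference_mask))))
  invisible(x)
}

## Read a single-channel raster (PNG or TIFF by extension) as a numeric
## matrix; multi-channel images are reduced to their first channel.
read_mask_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '", ext, "' (expected png or tiff): ",
         path)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

## Nearest-neighbour resampling of a matrix to n x n (preserves binarity).
resample_nearest <- function(m, n) {
  if (all(dim(m) == c(n, n))) return(m)
  ri <- pmin(dim(m)[1L], floor((seq_len(n) - 0.5) / n * dim(m)[1L]) + 1L)
  ci <- pmin(dim(m)[2L], floor((seq_len(n) - 0.5) / n * dim(m)[2L]) + 1L)
  m[ri, ci, drop = FALSE]
}

#' Load a vascular domain from raster mask images
#'
#' Reads co-registered single-channel raster images (PNG or TIFF) of the
#' vessel, perfusion and total-tumor masks (plus an optional reference
#' hypoxia mask), binarizes them (any value greater than zero is true),
#' resamples them to the solver grid by nearest neighbour if needed, and
#' derives the perfused-vessel map.
#'
#' @param vessel_path,perfusion_path,tumor_path Paths to raster images.
#' @param hypoxia_path Optional path to a reference hypoxia mask image.
#' @param geometry Target [grid_geometry()].
#' @return A [vascular_domain()].
#' @export
load_domain <- function(vessel_path, perfusion_path, tumor_path,
                        hypoxia_path = NULL, geometry = grid_geometry()) {
  imgs <- lapply(c(vessel = vessel_path, perfusion = perfusion_path,
                   tumor = tumor_path), read_mask_image)
  if (!is.null(hypoxia_path)) imgs$hypoxia <- read_mask_image(hypoxia_path)
  dims <- vapply(imgs, function(m) dim(m)[1:2], integer(2L))
  if (any(dims != dims[, 1L]))
    stop("mask images have mismatched pixel dimensions: ",
         paste(apply(dims, 2, paste, collapse = "x"), collapse = ", "))
  masks <- lapply(imgs, function(m) resample_nearest(m > 0, geometry$n))
  vascular_domain(masks$vessel, masks$perfusion, masks$tumor, geometry,
                  hypoxia_reference_mask = masks$hypoxia)
}

#' Write a vascular domain as a directory of PNG masks
#'
#' Serializes a domain as one PNG file per mask plus a JSON sidecar with
#' the grid geometry; the layout round-trips through [read_domain()].
#'
#' @param domain A [vascular_domain()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_domain <- function(domain, dir) {
  stopifnot(inherits(domain, "vascular_domain"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  masks <- c("vessel_mask", "perfusion_mask", "tumor_mask")
  if (!is.null(domain$hypoxia_reference_mask))
    masks <- c(masks, "hypoxia_reference_mask")
  for (m in masks) {
    png::writePNG(domain[[m]] * 1, file.path(dir, paste0(m, ".png")))
  }
  g <- domain$geometry
  jsonlite::write_json(
    list(extent_mm = g$extent_mm, n = g$n),
    file.path(dir, "geometry.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a vascular domain written by [write_domain()]
#'
#' @param dir Directory containing the PNG masks and `geometry.json`.
#' @return A [vascular_domain()].
#' @export
read_domain <- function(dir) {
  g <- jsonlite::read_json(file.path(dir, "geometry.json"),
                           simplifyVector = TRUE)
  geometry <- grid_geometry(extent_mm = g$extent_mm, n = g$n)
  hyp_path <- file.path(dir, "hypoxia_reference_mask.png")
  load_domain(file.path(dir, "vessel_mask.png"),
              file.path(dir, "perfusion_mask.png"),
              file.path(dir, "tumor_mask.png"),
              hypoxia_path = if (file.exists(hyp_path)) hyp_path,
              geometry = geometry)
}

#' Fraction of the tumor area occupied by perfused vessels
#'
#' @param domain A [vascular_domain()].
#' @return The number of perfused cells inside the tumor mask divided by
#'   the number of tumor cells, in `[0, 1]`.
#' @export
perfused_vascular_fraction <- function(domain) {
  stopifnot(inherits(domain, "vascular_domain"))
  sum(domain$perfused_mask & domain$tumor_mask) / sum(domain$tumor_mask)
}
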