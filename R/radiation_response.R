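#' Radiosensitivity parameters for the oxygen-modified LQ model
#'
#' Linear-quadratic radiosensitivity coefficients together with the
#' oxygen-enhancement parameters. The defaults (`alpha = 0.3` per Gy,
#' `beta = 0.03` per Gy^2) give 48% survival at 2 Gy under
#' well-oxygenated conditions; `OER_m = 3` is the maximum enhancement
#' ratio and `K_m = 3` mm Hg the oxygen tension at half-maximal
#' enhancement. A single enhancement ratio is applied to both the linear
#' and quadratic terms.
#'
#' @param alpha Linear coefficient (1/Gy).
#' @param beta Quadratic coefficient (1/Gy^2).
#' @param OER_m Maximum oxygen enhancement ratio (>= 1).
#' @param K_m Oxygen tension at half-maximal enhancement (mm Hg, > 0).
#' @return An object of class `radiosensitivity_params`.
#' @export
radiosensitivity_params <- function(alpha = 0.3, beta = 0.03,
                                    OER_m = 3, K_m = 3) {
  stopifnot(alpha >= 0, beta >= 0, OER_m >= 1, K_m > 0)
  structure(list(alpha = alpha, beta = beta, OER_m = OER_m, K_m = K_m),
            class = "radiosensitivity_params")
}

#' Oxygen modification factor
#'
#' Normalized oxygen enhancement ratio
#' \deqn{OMF(pO_2) = \frac{1}{OER_m}
#'   \frac{OER_m \cdot pO_2 + K_m}{pO_2 + K_m},}
#' a factor in `[1/OER_m, 1)` that scales the effective radiation dose:
#' `1/OER_m` under anoxia, rising steeply over 0--10 mm Hg and
#' approaching 1 at high oxygen tension.
#'
#' @param pO2 Oxygen tension (mm Hg, >= 0); vectorized. `Inf` returns the
#'   well-oxygenated limit 1.
#' @param params A [radiosensitivity_params()].
#' @return Dimensionless factor(s) in `[1/OER_m, 1]`.
#' @export
omf <- function(pO2, params = radiosensitivity_params()) {
  if (any(pO2 < 0, na.rm = TRUE)) stop("pO2 must be nonnegative")
  out <- (params$OER_m * pO2 + params$K_m) /
    (params$OER_m * (pO2 + params$K_m))
  out[is.infinite(pO2)] <- 1
  out
}

#' Cell survival after a single dose under a given oxygen tension
#'
#' Oxygen-modified linear-quadratic survival
#' \deqn{S = \exp[-\alpha \cdot OMF \cdot D - \beta (OMF \cdot D)^2].}
#' At full oxygenation (`OMF = 1`) this reduces to the plain LQ model
#' `exp(-alpha D - beta D^2)`.
#'
#' @param D Radiation dose (Gy, >= 0); vectorized.
#' @param pO2 Oxygen tension (mm Hg); `Inf` (default) for the
#'   well-oxygenated limit.
#' @param params A [radiosensitivity_params()].
#' @return Surviving fraction(s) in `(0, 1]`.
#' @export
survival_fraction <- function(D, pO2 = Inf,
                              params = radiosensitivity_params()) {
  if (any(D < 0, na.rm = TRUE)) stop("dose must be nonnegative")
  eff <- omf(pO2, params) * D
  exp(-params$alpha * eff - params$beta * eff^2)
}

#' Survival of a heterogeneous population: weighted average over
#' compartments
#'
#' Evaluates the oxygen-modified LQ survival in every compartment of an
#' oxygen profile (grid cells, histogram bins, or classes) and returns
#' the weighted mean
#' \deqn{SF = \sum_{ij} w_{ij} S(pO_{2,ij}) / \sum_{ij} w_{ij}.}
#'
#' @param pO2 Numeric vector (or matrix) of per-compartment oxygen
#'   tensions (mm Hg).
#' @param D Radiation dose (Gy, scalar).
#' @param params A [radiosensitivity_params()].
#' @param weights Nonnegative compartment weights with positive sum;
#'   default all 1.
#' @return Surviving fraction in `(0, 1]`.
#' @export
weighted_survival <- function(pO2, D, params = radiosensitivity_params(),
                              weights = NULL) {
  pO2 <- as.numeric(pO2)
  w <- if (is.null(weights)) rep.int(1, length(pO2)) else as.numeric(weights)
  stopifnot(length(w) == length(pO2), all(w >= 0))
  if (sum(w) == 0) stop("weights must have a positive sum")
  sum(w * survival_fraction(D, pO2, params)) / sum(w)
}

## Map a relative oxygen field to mm Hg: the field maximum is assigned
## pO2_max (default 100 mm Hg, the span of the 20 x 5 mm Hg histogram).
field_to_pO2 <- function(K, tumor_mask, pO2_max = 100) {
  K_max <- max(K)
  if (K_max <= 0) stop("degenerate field: maximum oxygen is zero")
  K[tumor_mask] / K_max * pO2_max
}

#' Histogram of tumor oxygen tensions
#'
#' Bins the tumor cells of a (relative) oxygen field into 20 bins of
#' 5 mm Hg covering 0--100 mm Hg, after scaling the field maximum to
#' `pO2_max`. Bins are `[5(i-1), 5i)` with the last bin closed.
#'
#' @param K Oxygen field matrix.
#' @param tumor_mask Logical matrix.
#' @param pO2_max Oxygen tension assigned to the field maximum (mm Hg).
#' @return A list with `counts` (length 20), `mids` (bin centres) and
#'   `breaks`.
#' @export
pO2_histogram <- function(K, tumor_mask, pO2_max = 100) {
  p <- field_to_pO2(K, tumor_mask, pO2_max)
  breaks <- seq(0, 100, by = 5)
  idx <- pmin(findInterval(p, breaks, rightmost.closed = TRUE), 20L)
  counts <- tabulate(idx, nbins = 20L)
  list(counts = counts, mids = breaks[-21] + 2.5, breaks = breaks)
}

#' Survival curves for six oxygenation scenarios
#'
#' Evaluates oxygen-modified LQ survival over a dose grid for six oxygen
#' profiles derived from one simulated field:
#' \describe{
#'   \item{normoxic}{uniform 60 mm Hg.}
#'   \item{anoxic}{uniform 0 mm Hg.}
#'   \item{hypoxic}{uniform 5 mm Hg (moderate hypoxia).}
#'   \item{binary}{each tumor cell classed hypoxic (`pO2 <= 5`,
#'     represented at 5 mm Hg) or normoxic (`> 5`, represented at
#'     60 mm Hg), weighted by class occupancy.}
#'   \item{histogram}{the 20-bin, 5 mm Hg histogram of the field, bins
#'     represented at their centres (configurable to the left edge) and
#'     weighted by bin counts.}
#'   \item{heterogeneous}{the full per-cell oxygen map.}
#' }
#' The field is mapped to mm Hg by scaling its maximum to `pO2_max`.
#'
#' @param K Converged oxygen field matrix.
#' @param tumor_mask Logical matrix.
#' @param doses Numeric vector of doses (Gy).
#' @param params A [radiosensitivity_params()].
#' @param pO2_max Oxygen tension assigned to the field maximum (mm Hg).
#' @param hypoxic_rep,normoxic_rep Representative tensions of the two
#'   classes of the binary scenario (mm Hg).
#' @param binary_cut Class boundary of the binary scenario (mm Hg).
#' @param bin_rep `"center"` or `"left"`: histogram bin representative.
#' @return A data frame with columns `scenario`, `dose`, `SF`.
#' @export
scenario_curves <- function(K, tumor_mask, doses = seq(0, 10, by = 0.5),
                            params = radiosensitivity_params(),
                            pO2_max = 100, hypoxic_rep = 5,
                            normoxic_rep = 60, binary_cut = 5,
                            bin_rep = c("center", "left")) {
  bin_rep <- match.arg(bin_rep)
  stopifnot(length(doses) >= 1L)
  p_cell <- field_to_pO2(K, tumor_mask, pO2_max)
  hist <- pO2_histogram(K, tumor_mask, pO2_max)
  bin_p <- if (bin_rep == "center") hist$mids else hist$breaks[-21]
  n_hyp <- sum(p_cell <= binary_cut)
  n_norm <- length(p_cell) - n_hyp
  profiles <- list(
    normoxic = list(p = normoxic_rep, w = 1),
    anoxic = list(p = 0, w = 1),
    hypoxic = list(p = hypoxic_rep, w = 1),
    binary = list(p = c(hypoxic_rep, normoxic_rep), w = c(n_hyp, n_norm)),
    histogram = list(p = bin_p, w = hist$counts),
    heterogeneous = list(p = p_cell, w = NULL)
  )
  out <- lapply(names(profiles), function(nm) {
    pr <- profiles[[nm]]
    data.frame(
      scenario = nm, dose = doses,
      SF = vapply(doses, function(D)
        weighted_survival(pr$p, D, params, weights = pr$w), 0))
  })
  do.call(rbind, out)
}
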