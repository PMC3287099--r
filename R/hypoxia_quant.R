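#' Relative hypoxia threshold
#'
#' Hypoxia is defined relative to the current field maximum: a cell is
#' hypoxic at level `pct` when its oxygen concentration falls below
#' `pct`% of the maximum concentration over the grid. The conventional
#' levels are 2.5 (severe, HP2.5), 5 (moderate, HP5) and 10 (mild, HP10),
#' but any value in (0, 100) is accepted.
#'
#' @param pct Percentage of the field maximum, in (0, 100).
#' @return An object of class `hypoxia_threshold` with fields `pct` and a
#'   derived `label` such as `"HP5"`.
#' @export
hypoxia_threshold <- function(pct) {
  stopifnot(is.numeric(pct), length(pct) == 1L, pct > 0, pct < 100)
  structure(list(pct = as.numeric(pct),
                 label = paste0("HP", format(pct, trim = TRUE))),
            class = "hypoxia_threshold")
}

as_threshold <- function(x) {
  if (inherits(x, "hypoxia_threshold")) x else hypoxia_threshold(x)
}

#' Binary hypoxia mask at a relative threshold
#'
#' Marks tumor cells whose oxygen concentration is strictly below
#' `pct`% of the maximum concentration. By default the maximum is taken
#' over the whole grid; set `max_over_tumor = TRUE` to restrict it to the
#' tumor mask. A field that is identically zero over the reference region
#' is degenerate: every tumor cell is hypoxic and the result carries
#' `attr(, "degenerate") = TRUE`.
#'
#' @param K Nonnegative numeric matrix, the oxygen field.
#' @param tumor_mask Logical matrix of the same shape.
#' @param threshold A [hypoxia_threshold()] or bare percentage.
#' @param max_over_tumor Take the reference maximum over the tumor mask
#'   only, instead of the whole grid.
#' @return Logical matrix marking hypoxic tumor cells.
#' @export
hypoxic_mask <- function(K, tumor_mask, threshold,
                         max_over_tumor = FALSE) {
  threshold <- as_threshold(threshold)
  stopifnot(is.matrix(K), all(dim(K) == dim(tumor_mask)))
  K_max <- if (max_over_tumor) max(K[tumor_mask]) else max(K)
  if (K_max <= 0) {
    out <- tumor_mask & TRUE
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tumor_mask & (K < threshold$pct / 100 * K_max)
}

#' Hypoxic fraction of the tumor area
#'
#' Fraction of tumor cells that are hypoxic at a relative threshold; the
#' area analogue of a stained-section hypoxia measurement.
#'
#' @inheritParams hypoxic_mask
#' @return A fraction in `[0, 1]`.
#' @export
hypoxic_area_fraction <- function(K, tumor_mask, threshold,
                                  max_over_tumor = FALSE) {
  n_tumor <- sum(tumor_mask)
  if (n_tumor == 0L) stop("empty domain: tumor mask has no positive cells")
  sum(hypoxic_mask(K, tumor_mask, threshold, max_over_tumor)) / n_tumor
}

#' Pixel-wise spatial agreement between two hypoxia masks
#'
#' Percentage of tumor cells on which a simulated hypoxia mask and a
#' reference mask agree (both hypoxic or both oxic). Symmetric in the two
#' masks. A Jaccard overlap (intersection over union of the hypoxic
#' regions) is available as an alternative statistic.
#'
#' @param sim_mask,ref_mask Logical matrices, co-registered.
#' @param tumor_mask Logical matrix restricting the comparison; use an
#'   all-true matrix to compare over the full frame.
#' @param method `"agreement"` (percent matching cells, the default) or
#'   `"jaccard"` (percent intersection over union).
#' @return A percentage in `[0, 100]`.
#' @export
spatial_agreement <- function(sim_mask, ref_mask, tumor_mask,
                              method = c("agreement", "jaccard")) {
  method <- match.arg(method)
  if (!all(dim(sim_mask) == dim(ref_mask)) ||
      !all(dim(sim_mask) == dim(tumor_mask)))
    stop("masks must share dimensions")
  s <- sim_mask[tumor_mask]
  r <- ref_mask[tumor_mask]
  if (length(s) == 0L) stop("empty domain: tumor mask has no positive cells")
  if (method == "agreement") {
    100 * mean(s == r)
  } else {
    u <- sum(s | r)
    if (u == 0L) 100 else 100 * sum(s & r) / u
  }
}

#' Hypoxia report for one tumor cross-section
#'
#' Collects, per relative threshold, the hypoxic area fraction, the
#' electrode-estimated hypoxic fraction (when a sampling plan is given),
#' and the spatial agreement with the domain's reference hypoxia mask
#' (when present).
#'
#' @param field A solved field state (see [solve_to_stationary_hypoxia()]).
#' @param domain The [vascular_domain()] the field was solved on.
#' @param thresholds Numeric vector of relative thresholds (percent).
#' @param plan Optional [make_plan()] sampling plan for the electrode
#'   estimate.
#' @return An object of class `hypoxia_report`: a list with `hp_area`,
#'   `hp_electrode` (or `NULL`) and `spatial_agreement_pct` (or `NULL`),
#'   each a named numeric vector keyed by threshold label.
#' @export
hypoxia_report <- function(field, domain, thresholds = c(2.5, 5, 10),
                           plan = NULL) {
  th <- lapply(thresholds, hypoxia_threshold)
  labels <- vapply(th, `[[`, "", "label")
  hp_area <- vapply(th, function(t)
    hypoxic_area_fraction(field$K, domain$tumor_mask, t), 0)
  names(hp_area) <- labels
  hp_electrode <- NULL
  if (!is.null(plan)) {
    readings <- sample_readings(plan, field$K, domain$geometry,
                                tumor_mask = domain$tumor_mask)
    hp_electrode <- hp_from_readings(readings, max(field$K), thresholds)
  }
  agreement <- NULL
  if (!is.null(domain$hypoxia_reference_mask)) {
    agreement <- vapply(th, function(t)
      spatial_agreement(hypoxic_mask(field$K, domain$tumor_mask, t),
                        domain$hypoxia_reference_mask,
                        domain$tumor_mask), 0)
    names(agreement) <- labels
  }
  structure(list(hp_area = hp_area, hp_electrode = hp_electrode,
                 spatial_agreement_pct = agreement,
                 thresholds = thresholds),
            class = "hypoxia_report")
}

#' @export
print.hypoxia_report <- function(x, ...) {
  cat("<hypoxia_report>\n  area fractions: ",
      paste(sprintf("%s=%.3f", names(x$hp_area), x$hp_area),
            collapse = "  "), "\n", sep = "")
  if (!is.null(x$hp_electrode))
    cat("  electrode fractions: ",
        paste(sprintf("%s=%.3f", names(x$hp_electrode), x$hp_electrode),
              collapse = "  "), "\n", sep = "")
  if (!is.null(x$spatial_agreement_pct))
    cat("  agreement vs reference (%): ",
        paste(sprintf("%s=%.1f", names(x$spatial_agreement_pct),
                      x$spatial_agreement_pct), collapse = "  "),
        "\n", sep = "")
  invisible(x)
}
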