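#' One-way variance-components decomposition of electrode readings
#'
#' Partitions pooled per-tumor readings into within-tumor and
#' between-tumor variance components by the method of moments (ANOVA
#' estimators): the within component is the pooled within-group mean
#' square, the between component is `max(0, (MS_between - MS_within) /
#' n0)` with the standard unbalanced-design coefficient `n0`. The
#' percentage of total variance contributed by within-tumor variation is
#'
#' \deqn{100 \cdot Var(within) / (Var(between) + Var(within)).}
#'
#' With `scale = "mean"` the within component entering the percentage is
#' the within-tumor variance of the estimated tumor mean,
#' `MS_within / n0`, which shrinks as readings accumulate; this is the
#' quantity that answers how many tracks are needed before a single
#' tumor's oxygenation estimate is reliable relative to the spread
#' between tumors. `scale = "reading"` uses the raw per-reading
#' component.
#'
#' @param values Numeric vector of readings, pooled over tracks.
#' @param tumor Grouping vector (one entry per reading) identifying the
#'   tumor each reading came from.
#' @param scale `"mean"` (default) or `"reading"`; see Details.
#' @return An object of class `variance_decomposition` with fields
#'   `var_within`, `var_between`, `n0`, `pct_total_within`, `scale` and a
#'   `degenerate` flag (set when both components are zero, in which case
#'   the percentage is 0 by convention).
#' @export
within_between <- function(values, tumor, scale = c("mean", "reading")) {
  scale <- match.arg(scale)
  tumor <- factor(tumor)
  if (nlevels(tumor) < 2L)
    stop("insufficient data: need readings from at least 2 tumors")
  n_i <- table(tumor)
  if (any(n_i < 2L))
    stop("insufficient data: every tumor needs at least 2 readings")
  N <- length(values)
  T_ <- nlevels(tumor)
  ms <- suppressWarnings(stats::anova(stats::aov(values ~ tumor)))
  MS_between <- ms["tumor", "Mean Sq"]
  MS_within <- ms["Residuals", "Mean Sq"]
  n0 <- (N - sum(n_i^2) / N) / (T_ - 1)
  var_within <- MS_within
  var_between <- max(0, (MS_between - MS_within) / n0)
  vw <- if (scale == "mean") var_within / n0 else var_within
  total <- vw + var_between
  # 0/0 convention: near-zero total variance (relative to the data scale)
  # is reported as a degenerate 0% share
  degenerate <- total <= 1e-12 * max(1, mean(values^2))
  structure(
    list(var_within = var_within, var_between = var_between, n0 = n0,
         pct_total_within = if (degenerate) 0 else 100 * vw / total,
         scale = scale, n_tumors = T_, n_readings = N,
         degenerate = degenerate),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(paste0(
    "<variance_decomposition> %d tumors, %d readings\n",
    "  within: %.4g  between: %.4g  within %% of total (%s scale): %.1f\n"),
    x$n_tumors, x$n_readings, x$var_within, x$var_between, x$scale,
    x$pct_total_within))
  invisible(x)
}

#' Within-tumor variance share as a function of track count
#'
#' For each track count `k = 1 .. max_tracks`, samples every tumor of a
#' solved cohort along the first `k` tracks of a `max_tracks`-track plan,
#' decomposes the pooled readings with [within_between()], and reports
#' the within-tumor percentage of total variance. Random strategies are
#' averaged over seeded replicates; the uniform and radial layouts are
#' deterministic.
#'
#' @param cohort A [solve_cohort()] result (list of `domain` + `field`
#'   pairs).
#' @param strategy Track placement strategy, see [make_plan()].
#' @param max_tracks Largest track count examined (>= 2).
#' @param replicates Number of seeded replicates to average over.
#' @param seed Master seed for plan randomness.
#' @param step_mm,n_readings,arc_deg Passed to [make_plan()].
#' @param scale Variance scale passed to [within_between()].
#' @return A data frame with columns `strategy`, `n_tracks`,
#'   `pct_total_within`.
#' @export
variance_vs_tracks <- function(cohort, strategy = "uniform",
                               max_tracks = 8L, replicates = 1L,
                               seed = 1L, step_mm = 0.2, n_readings = 25L,
                               arc_deg = c(60, 120),
                               scale = c("mean", "reading")) {
  scale <- match.arg(scale)
  max_tracks <- as.integer(max_tracks)
  stopifnot(max_tracks >= 2L)
  acc <- matrix(0, nrow = max_tracks, ncol = replicates)
  for (rep in seq_len(replicates)) {
    readings <- lapply(seq_along(cohort), function(ti) {
      plan <- make_plan(strategy, max_tracks, cohort[[ti]]$domain,
                        seed = derive_seed(seed, strategy, rep, ti),
                        step_mm = step_mm, n_readings = n_readings,
                        arc_deg = arc_deg)
      sample_readings(plan, cohort[[ti]]$field$K,
                      cohort[[ti]]$domain$geometry,
                      tumor_mask = cohort[[ti]]$domain$tumor_mask)
    })
    for (k in seq_len(max_tracks)) {
      v <- unlist(lapply(readings, function(r) r$value[r$track <= k]))
      g <- unlist(lapply(seq_along(readings), function(ti)
        rep.int(ti, sum(readings[[ti]]$track <= k))))
      acc[k, rep] <- within_between(v, g, scale = scale)$pct_total_within
    }
  }
  data.frame(strategy = strategy, n_tracks = seq_len(max_tracks),
             pct_total_within = rowMeans(acc))
}

#' Between-methods variance share for paired hypoxia estimates
#'
#' Compares two per-tumor hypoxia estimates -- typically the area method
#' and the electrode method -- with a two-factor (tumor x method, one
#' observation per cell, no interaction) mean-square decomposition. The
#' method and tumor variance components are method-of-moments estimates
#' truncated at zero, and the reported statistic is
#'
#' \deqn{100 \cdot Var(between\ methods) /
#'   (Var(between\ tumors) + Var(between\ methods)),}
#'
#' the share of total variance attributable to disagreement between the
#' two estimation methods. Small values mean the electrode protocol
#' reproduces the area-based hypoxic fraction.
#'
#' @param hp_area,hp_electrode Numeric vectors of per-tumor hypoxic
#'   fractions from the two methods, same tumors in the same order
#'   (length >= 2).
#' @return A list with `var_method`, `var_tumor`, `pct_total_methods` and
#'   a `degenerate` flag (percentage 0 by convention when both
#'   components vanish).
#' @export
between_methods <- function(hp_area, hp_electrode) {
  T_ <- length(hp_area)
  if (length(hp_electrode) != T_)
    stop("mismatched tumor sets: ", T_, " area vs ", length(hp_electrode),
         " electrode estimates")
  if (T_ < 2L) stop("insufficient data: need at least 2 tumors")
  y <- c(hp_area, hp_electrode)
  tumor <- factor(rep(seq_len(T_), 2L))
  method <- factor(rep(c("area", "electrode"), each = T_))
  ms <- suppressWarnings(stats::anova(stats::aov(y ~ tumor + method)))
  MS_tumor <- ms["tumor", "Mean Sq"]
  MS_method <- ms["method", "Mean Sq"]
  MS_resid <- ms["Residuals", "Mean Sq"]
  var_method <- max(0, (MS_method - MS_resid) / T_)
  var_tumor <- max(0, (MS_tumor - MS_resid) / 2)
  total <- var_method + var_tumor
  degenerate <- total <= 1e-12 * max(1, mean(y^2))
  list(var_method = var_method, var_tumor = var_tumor,
       pct_total_methods = if (degenerate) 0 else 100 * var_method / total,
       degenerate = degenerate)
}

#' Normality diagnostics for reading residuals
#'
#' Summarizes residuals from per-tumor means: sample skewness, excess
#' kurtosis and a Shapiro-Wilk statistic. Variance-components analysis
#' assumes approximately normal errors; this check is advisory and never
#' blocks an analysis.
#'
#' @param values Numeric vector of readings.
#' @param tumor Optional grouping vector; residuals are taken from group
#'   means when given, from the overall mean otherwise.
#' @return A list with `skewness`, `kurtosis_excess`, `shapiro_w`,
#'   `p_value`, `n` and a `degenerate` flag for constant residuals.
#' @export
normality_check <- function(values, tumor = NULL) {
  res <- if (is.null(tumor)) values - mean(values)
  else values - stats::ave(values, factor(tumor))
  if (stats::var(res) == 0)
    return(list(skewness = NA_real_, kurtosis_excess = NA_real_,
                shapiro_w = NA_real_, p_value = NA_real_,
                n = length(res), degenerate = TRUE))
  m2 <- mean(res^2)
  sw <- stats::shapiro.test(if (length(res) > 5000)
    res[round(seq(1, length(res), length.out = 5000))] else res)
  list(skewness = mean(res^3) / m2^1.5,
       kurtosis_excess = mean(res^4) / m2^2 - 3,
       shapiro_w = unname(sw$statistic),
       p_value = sw$p.value,
       n = length(res), degenerate = FALSE)
}
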