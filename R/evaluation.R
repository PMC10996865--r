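#' Coefficient of determination between modelled and measured series
#'
#' Squared Pearson correlation, the goodness-of-fit measure used alongside
#' RMSE for model comparison. Affine-invariant: `measured = a*modelled + b`
#' gives 1 for any `a != 0`.
#'
#' @param modelled,measured Equal-length numeric series (length >= 3), both
#'   non-constant.
#' @return R-squared in \[0, 1\].
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 2))  # 0.75
r_squared <- function(modelled, measured) {
  if (length(modelled) != length(measured) || length(modelled) < 3)
    stop("'modelled' and 'measured' must be equal-length series of >= 3 points",
         call. = FALSE)
  if (sd(modelled) == 0 || sd(measured) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  cor(modelled, measured)^2
}

#' Compare two R-squared values by Fisher's r-to-z transformation
#'
#' Tests whether two coefficients of determination obtained on the same `n`
#' samples differ: `z = (atanh(sqrt(r2_a)) - atanh(sqrt(r2_b))) /
#' sqrt(2/(n-3))`. The correlation is taken as the positive root of each
#' R-squared. With `a` the without-slope and `b` the with-slope model, an
#' improvement from adding the slope gives a negative z. `|z| > 1.96`
#' is the conventional 5% significance threshold.
#'
#' @param r2_a,r2_b R-squared values in \[0, 1).
#' @param n Number of samples underlying both correlations (> 3).
#' @return The observed z value.
#' @export
#' @examples
#' fisher_z_compare(0.847, 0.847, 9)   # 0
#' fisher_z_compare(0.983, 0.998, 10)  # about -2.01
fisher_z_compare <- function(r2_a, r2_b, n) {
  if (n <= 3) stop("'n' must exceed 3", call. = FALSE)
  for (r2 in c(r2_a, r2_b)) {
    if (r2 < 0 || r2 > 1)
      stop("R-squared must lie in [0, 1]", call. = FALSE)
    if (r2 == 1)
      stop("R-squared of 1 has an infinite Fisher transform", call. = FALSE)
  }
  (atanh(sqrt(r2_a)) - atanh(sqrt(r2_b))) / sqrt(2 / (n - 3))
}

#' Squared correlation between two slope series
#'
#' Concordance of the fitted clearance-reduction slopes across paired
#' treatments (e.g. each patient's first vs second session), as a squared
#' Pearson correlation.
#'
#' @param slopes_a,slopes_b Equal-length numeric vectors (length >= 3), both
#'   non-constant.
#' @return R-squared in \[0, 1\].
#' @export
slope_correlation <- function(slopes_a, slopes_b) r_squared(slopes_a, slopes_b)

#' Summary of phosphate removal over a group of treatments
#'
#' Mean, sample SD (n-1 denominator) and normal-quantile 95% confidence
#' interval `mean +/- 1.96 SD/sqrt(n)` of per-treatment phosphate removal.
#'
#' @param removals Numeric vector of per-treatment removals, mmol (at least
#'   two values).
#' @param label Optional group label (e.g. `"HD1 without slope"`).
#' @return List of class `removal_summary`: `label`, `n`, `mean`, `sd`,
#'   `ci_low`, `ci_high` (mmol).
#' @export
removal_summary <- function(removals, label = NULL) {
  if (length(removals) < 2)
    stop("need at least 2 removals for an SD", call. = FALSE)
  m <- mean(removals)
  s <- sd(removals)
  half <- 1.96 * s / sqrt(length(removals))
  structure(list(label = label, n = length(removals), mean = m, sd = s,
                 ci_low = m - half, ci_high = m + half),
            class = "removal_summary")
}

#' @export
print.removal_summary <- function(x, ...) {
  cat(sprintf("%s: %.2f +/- %.2f mmol (95%% CI %.2f-%.2f, n = %d)\n",
              if (is.null(x$label)) "removal" else x$label,
              x$mean, x$sd, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Cohort medians of volumes, clearance, coefficients and slope
#'
#' Median summaries over all fitted treatments (median of two central order
#' statistics for even counts): `V1`, `V2`, `V3`, `kd`, `k1`, `k2` and the
#' slope, the latter both over all sessions and over the sessions with a
#' non-zero slope, plus the non-zero slope range and the count of zero-slope
#' sessions.
#'
#' @param param_table data.frame with columns `slope`, `V1`, `V2`, `V3`,
#'   `kd`, `k1`, `k2` (see [fit_parameter_table()]).
#' @return List with `V1`, `V2`, `V3`, `kd`, `k1`, `k2`, `slope_all`,
#'   `slope_nonzero`, `slope_nonzero_min`, `slope_nonzero_max`, `n_zero`,
#'   `n_sessions`.
#' @export
cohort_medians <- function(param_table) {
  needed <- c("slope", "V1", "V2", "V3", "kd", "k1", "k2")
  if (!is.data.frame(param_table) || nrow(param_table) == 0 ||
      !all(needed %in% names(param_table)))
    stop("'param_table' must be a non-empty data.frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  nz <- param_table$slope[param_table$slope > 0]
  list(V1 = median(param_table$V1), V2 = median(param_table$V2),
       V3 = median(param_table$V3), kd = median(param_table$kd),
       k1 = median(param_table$k1), k2 = median(param_table$k2),
       slope_all = median(param_table$slope),
       slope_nonzero = if (length(nz)) median(nz) else NA_real_,
       slope_nonzero_min = if (length(nz)) min(nz) else NA_real_,
       slope_nonzero_max = if (length(nz)) max(nz) else NA_real_,
       n_zero = sum(param_table$slope == 0),
       n_sessions = nrow(param_table))
}

#' Model-comparison table for a fitted cohort
#'
#' One row per session comparing the without-slope and with-slope fits:
#' sample count, fitted slope, RMSE and R-squared of each variant, the
#' observed Fisher z (negative when the slope improves the fit) and the
#' `|z| > 1.96` significance flag.
#'
#' @param fit_table A `phos_fit_table` from [fit_cohort()].
#' @return data.frame with columns `patient_id`, `session_id`, `n`, `slope`,
#'   `rmse_without`, `r2_without`, `rmse_with`, `r2_with`, `z_observed`,
#'   `significant`.
#' @export
build_comparison_table <- function(fit_table) {
  stopifnot(inherits(fit_table, "phos_fit_table"))
  if (length(fit_table$fits) == 0) stop("no fitted sessions", call. = FALSE)
  do.call(rbind, lapply(fit_table$fits, function(f) {
    if (is.null(f$without) || is.null(f$with))
      stop("each session needs both a without-slope and a with-slope fit",
           call. = FALSE)
    r2_wo <- r_squared(f$without$modelled, f$without$measured)
    r2_w <- r_squared(f$with$modelled, f$with$measured)
    # the transform diverges at R^2 = 1; cap just below (a fit this perfect
    # is numerically exact on the sampling grid)
    cap <- 1 - 1e-12
    z <- fisher_z_compare(min(r2_wo, cap), min(r2_w, cap), f$with$n_samples)
    data.frame(patient_id = f$patient_id, session_id = f$session_id,
               n = f$with$n_samples, slope = f$with$slc,
               rmse_without = f$without$rmse, r2_without = r2_wo,
               rmse_with = f$with$rmse, r2_with = r2_w,
               z_observed = z, significant = abs(z) > 1.96)
  }))
}
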