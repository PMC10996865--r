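#' Filter a dialysate sample series
#'
#' Drops dialysate samples that are not measurable (`NA`) or below the
#' outlier threshold of 0.10 mmol/L; sample order is preserved. The counts of
#' dropped samples are attached as attributes `dropped_unmeasurable` and
#' `dropped_outliers`.
#'
#' @param samples data.frame with columns `time_min`, `conc_mmol_l`
#'   (dialysate source; `NA` = not measurable).
#' @param threshold Outlier threshold in mmol/L (default 0.10); samples with
#'   concentration strictly below it are discarded.
#' @return The filtered data.frame. If every sample is removed an empty
#'   series is returned with a warning (downstream clearance estimation then
#'   fails).
#' @export
#' @examples
#' d <- data.frame(time_min = c(60, 120, 180),
#'                 conc_mmol_l = c(0.05, 0.30, 0.25))
#' filter_dialysate(d)  # keeps 0.30 and 0.25, drops one outlier
filter_dialysate <- function(samples, threshold = 0.10) {
  stopifnot(is.data.frame(samples),
            all(c("time_min", "conc_mmol_l") %in% names(samples)))
  unmeasurable <- is.na(samples$conc_mmol_l)
  outlier <- !unmeasurable & samples$conc_mmol_l < threshold
  kept <- samples[!(unmeasurable | outlier), , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0)
    warning("all dialysate samples removed by filtering", call. = FALSE)
  attr(kept, "dropped_unmeasurable") <- sum(unmeasurable)
  attr(kept, "dropped_outliers") <- sum(outlier)
  kept
}

#' Estimate the mean dialyser phosphate clearance
#'
#' Ratio estimator for the treatment-mean dialyser clearance kd:
#' `kd = (mean dialysate concentration * mean dialysate flow) /
#' mean plasma concentration`, where the plasma mean is over the plasma
#' samples taken at the dialysate sampling times. The two means may use
#' different sample counts after filtering. Each dialysate sample is paired
#' with the plasma sample at the same nominal time; failing that, the nearest
#' plasma sample within `pair_tol_min` minutes is used, and dialysate samples
#' with no plasma partner are excluded from both means.
#'
#' @param dialysate Filtered dialysate series (see [filter_dialysate()]).
#' @param plasma Plasma series (`time_min`, `conc_mmol_l`).
#' @param qd_l_h Mean dialysate flow in L/h.
#' @param pair_tol_min Pairing tolerance in minutes (default 5).
#' @return A list of class `kd_estimate`: `kd_l_h`, `n_d`, `n_p`,
#'   `mean_dialysate`, `mean_plasma`.
#' @export
#' @examples
#' d <- data.frame(time_min = c(60, 120, 180), conc_mmol_l = c(0.30, 0.25, 0.20))
#' p <- data.frame(time_min = c(60, 120, 180), conc_mmol_l = c(1.2, 1.0, 0.8))
#' estimate_kd(d, p, qd_l_h = 27)  # 6.75 L/h
estimate_kd <- function(dialysate, plasma, qd_l_h, pair_tol_min = 5) {
  stopifnot(is.data.frame(dialysate), is.data.frame(plasma))
  if (!is.numeric(qd_l_h) || length(qd_l_h) != 1L || qd_l_h <= 0)
    stop("'qd_l_h' must be a single positive flow", call. = FALSE)
  if (nrow(dialysate) == 0)
    stop("cannot estimate kd from an empty dialysate series", call. = FALSE)
  if (nrow(plasma) == 0)
    stop("cannot estimate kd without plasma samples", call. = FALSE)
  paired_plasma <- vapply(dialysate$time_min, function(t) {
    dt <- abs(plasma$time_min - t)
    i <- which.min(dt)
    if (dt[i] <= pair_tol_min) plasma$conc_mmol_l[i] else NA_real_
  }, numeric(1))
  keep <- !is.na(paired_plasma)
  if (!any(keep))
    stop("no dialysate sample has a plasma partner within the pairing tolerance",
         call. = FALSE)
  d <- dialysate$conc_mmol_l[keep]
  p <- paired_plasma[keep]
  mean_p <- mean(p)
  if (mean_p <= 0)
    stop("mean paired plasma concentration is zero; kd undefined", call. = FALSE)
  structure(
    list(kd_l_h = mean(d) * qd_l_h / mean_p,
         n_d = length(d), n_p = length(p),
         mean_dialysate = mean(d), mean_plasma = mean_p),
    class = "kd_estimate"
  )
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("<kd_estimate> kd = %.2f L/h (n_d = %d, n_p = %d)\n",
              x$kd_l_h, x$n_d, x$n_p))
  invisible(x)
}

#' Per-session dialyser clearance report
#'
#' Applies the dialysate filter and the ratio estimator to one treatment
#' session; returns the estimate together with the drop counts, as a list
#' ready for JSON serialisation.
#'
#' @param session An [hd_session()] object.
#' @param pair_tol_min Pairing tolerance in minutes (default 5).
#' @return List with `kd_l_h`, `n_d`, `n_p`, `dropped_outliers`,
#'   `dropped_unmeasurable`.
#' @export
session_kd <- function(session, pair_tol_min = 5) {
  stopifnot(inherits(session, "hd_session"))
  filtered <- filter_dialysate(session$dialysate)
  est <- estimate_kd(filtered, session$plasma,
                     qd_l_h = ml_min_to_l_h(session$qd_ml_min),
                     pair_tol_min = pair_tol_min)
  list(kd_l_h = est$kd_l_h, n_d = est$n_d, n_p = est$n_p,
       dropped_outliers = attr(filtered, "dropped_outliers"),
       dropped_unmeasurable = attr(filtered, "dropped_unmeasurable"))
}
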