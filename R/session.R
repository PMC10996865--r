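#' One haemodialysis treatment session
#'
#' Container for a single treatment: the patient, treatment settings and the
#' measured plasma and dialysate phosphate sample series. Times are minutes
#' from dialysis start; concentrations are mmol/L. The plasma series must
#' include the pre-dialytic sample at `time_min = 0`. Dialysate
#' concentrations may be `NA`, meaning the sample was not measurable (never
#' coded as zero).
#'
#' @param patient An [hd_patient()] object.
#' @param session_id Opaque treatment label (e.g. `"HD1"`).
#' @param duration_min Treatment duration in minutes (> 0).
#' @param qd_ml_min Mean dialysate flow in mL/min (> 0).
#' @param plasma data.frame with columns `time_min`, `conc_mmol_l`; strictly
#'   increasing times, non-negative concentrations, first sample at 0.
#' @param dialysate data.frame with columns `time_min`, `conc_mmol_l`;
#'   strictly increasing times; `NA` flags a not-measurable sample.
#' @return An object of class `hd_session`.
#' @export
hd_session <- function(patient, session_id, duration_min, qd_ml_min,
                       plasma, dialysate) {
  stopifnot(inherits(patient, "hd_patient"))
  if (!is.numeric(duration_min) || duration_min <= 0)
    stop("'duration_min' must be positive", call. = FALSE)
  if (!is.numeric(qd_ml_min) || qd_ml_min <= 0)
    stop("'qd_ml_min' must be positive", call. = FALSE)
  check_series <- function(df, what, allow_na) {
    if (!is.data.frame(df) || !all(c("time_min", "conc_mmol_l") %in% names(df)))
      stop(what, " series needs columns 'time_min' and 'conc_mmol_l'",
           call. = FALSE)
    if (nrow(df) > 1 && any(diff(df$time_min) <= 0))
      stop(what, " sample times must be strictly increasing", call. = FALSE)
    bad <- !is.na(df$conc_mmol_l) & df$conc_mmol_l < 0
    if (any(bad))
      stop(what, " series has negative concentration at row ",
           which(bad)[1], call. = FALSE)
    if (!allow_na && anyNA(df$conc_mmol_l))
      stop(what, " series must not contain missing concentrations",
           call. = FALSE)
    df[, c("time_min", "conc_mmol_l")]
  }
  plasma <- check_series(plasma, "plasma", allow_na = FALSE)
  dialysate <- check_series(dialysate, "dialysate", allow_na = TRUE)
  if (nrow(plasma) == 0 || plasma$time_min[1] != 0)
    stop("plasma series must start with the pre-dialytic sample at time 0",
         call. = FALSE)
  structure(
    list(patient = patient, session_id = as.character(session_id),
         duration_min = as.numeric(duration_min),
         qd_ml_min = as.numeric(qd_ml_min),
         plasma = plasma, dialysate = dialysate),
    class = "hd_session"
  )
}

#' @export
print.hd_session <- function(x, ...) {
  cat(sprintf(
    "<hd_session %s/%s> %.0f min, Qd %.0f mL/min, %d plasma / %d dialysate samples\n",
    x$patient$patient_id, x$session_id, x$duration_min, x$qd_ml_min,
    nrow(x$plasma), nrow(x$dialysate)))
  invisible(x)
}

#' Convert a volumetric flow or clearance from mL/min to L/h
#'
#' @param x Flow in mL/min.
#' @return Flow in L/h (`x * 0.06`).
#' @export
ml_min_to_l_h <- function(x) x * 0.06
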