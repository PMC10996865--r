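#' Patient demographics for anthropometric volume determination
#'
#' Bundles the fields the Watson total-body-water formula needs. The
#' pre-dialytic weight is used as the body-weight input, i.e. intradialytic
#' ultrafiltration is ignored and distribution volumes are held constant over
#' a session.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_y Age in years (> 0). Required for males; the female Watson
#'   equation does not use age, but a positive value must still be supplied
#'   when present.
#' @param height_cm Height in cm (> 0).
#' @param weight_pre_kg Pre-dialytic body weight in kg (> 0).
#' @param patient_id Opaque label identifying the patient.
#'
#' @return An object of class `hd_patient`.
#' @seealso [watson_tbw()], [partition_volumes()]
#' @export
#' @examples
#' hd_patient("male", age_y = 70, height_cm = 160, weight_pre_kg = 80)
hd_patient <- function(sex, age_y, height_cm, weight_pre_kg,
                       patient_id = "P1") {
  sex <- match.arg(sex, c("male", "female"))
  for (nm in c("age_y", "height_cm", "weight_pre_kg")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  structure(
    list(sex = sex, age_y = as.numeric(age_y),
         height_cm = as.numeric(height_cm),
         weight_pre_kg = as.numeric(weight_pre_kg),
         patient_id = as.character(patient_id)),
    class = "hd_patient"
  )
}

#' @export
print.hd_patient <- function(x, ...) {
  cat(sprintf("<hd_patient %s> %s, %.0f y, %.0f cm, %.1f kg (pre-dialytic)\n",
              x$patient_id, x$sex, x$age_y, x$height_cm, x$weight_pre_kg))
  invisible(x)
}

#' Watson total body water
#'
#' Anthropometric estimate of total body water (TBW) in litres from sex, age,
#' height and (pre-dialytic) weight:
#' males `2.447 - 0.09156 age + 0.1074 height + 0.3362 weight`,
#' females `-2.097 + 0.1069 height + 0.2466 weight`.
#'
#' @param patient An [hd_patient()] object.
#' @return TBW in litres.
#' @export
#' @examples
#' watson_tbw(hd_patient("male", 70, 160, 80))   # 40.118 L
#' watson_tbw(hd_patient("female", 60, 160, 72)) # 32.762 L
watson_tbw <- function(patient) {
  stopifnot(inherits(patient, "hd_patient"))
  tbw <- if (patient$sex == "male") {
    2.447 - 0.09156 * patient$age_y + 0.1074 * patient$height_cm +
      0.3362 * patient$weight_pre_kg
  } else {
    -2.097 + 0.1069 * patient$height_cm + 0.2466 * patient$weight_pre_kg
  }
  if (!is.finite(tbw) || tbw <= 0)
    stop("degenerate anthropometry: Watson TBW is not positive", call. = FALSE)
  tbw
}

#' Partition total body water into the three distribution volumes
#'
#' TBW is split with an extracellular:intracellular ratio of 1:2; the plasma
#' water compartment V1 is one quarter of the extracellular fluid, V2 is the
#' remaining extracellular fluid and V3 the intracellular fluid. Hence
#' `V1 = TBW/12`, `V2 = TBW/4`, `V3 = 2 TBW/3`, and `V1 + V2 + V3 = TBW`
#' with a fixed 1:3:8 ratio.
#'
#' @param tbw Total body water in litres (>= 0).
#' @return An object of class `hd_volumes` with fields `V1`, `V2`, `V3` (L).
#' @export
#' @examples
#' partition_volumes(33.85)  # V1 2.82, V2 8.46, V3 22.57
partition_volumes <- function(tbw) {
  if (!is.numeric(tbw) || length(tbw) != 1L || !is.finite(tbw) || tbw < 0)
    stop("'tbw' must be a single non-negative number", call. = FALSE)
  structure(list(V1 = tbw / 12, V2 = tbw / 4, V3 = 2 * tbw / 3),
            class = "hd_volumes")
}

#' @export
print.hd_volumes <- function(x, ...) {
  cat(sprintf("<hd_volumes> V1 = %.2f L, V2 = %.2f L, V3 = %.2f L (TBW %.2f L)\n",
              x$V1, x$V2, x$V3, x$V1 + x$V2 + x$V3))
  invisible(x)
}

#' Distribution volumes for a patient
#'
#' Convenience wrapper: Watson TBW followed by the 1:3:8 partition.
#'
#' @inheritParams watson_tbw
#' @return An `hd_volumes` object.
#' @export
patient_volumes <- function(patient) partition_volumes(watson_tbw(patient))
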