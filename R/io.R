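#' Read treatment sessions from a CSV or JSON file
#'
#' The flat session schema has one row per sample with columns `patient_id`,
#' `session_id`, `sex`, `age_y`, `height_cm`, `weight_pre_kg`,
#' `duration_min`, `qd_ml_min`, `sample_type` (`"plasma"` or `"dialysate"`),
#' `time_min`, `conc_mmol_l`. Times are minutes from dialysis start and
#' concentrations mmol/L; an empty/`NA` concentration on a dialysate row
#' flags a not-measurable sample. Files ending in `.json` hold the same
#' table as an array of objects.
#'
#' @param path Path to the session file.
#' @return List of [hd_session()] objects, in file order.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("patient_id", "session_id", "sex", "age_y", "height_cm",
                "weight_pre_kg", "duration_min", "qd_ml_min", "sample_type",
                "time_min", "conc_mmol_l")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("session file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!is.na(df$conc_mmol_l) & df$conc_mmol_l < 0)
  if (length(bad))
    stop("negative concentration at row ", bad[1], " of ", path,
         call. = FALSE)
  bad_type <- which(!df$sample_type %in% c("plasma", "dialysate"))
  if (length(bad_type))
    stop("unknown sample_type at row ", bad_type[1], " of ", path,
         call. = FALSE)
  keys <- unique(df[, c("patient_id", "session_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    rows <- df[df$patient_id == keys$patient_id[i] &
               df$session_id == keys$session_id[i], ]
    patient <- hd_patient(rows$sex[1], rows$age_y[1], rows$height_cm[1],
                          rows$weight_pre_kg[1],
                          patient_id = as.character(keys$patient_id[i]))
    pick <- function(type) {
      out <- rows[rows$sample_type == type, c("time_min", "conc_mmol_l")]
      out <- out[order(out$time_min), ]
      rownames(out) <- NULL
      out
    }
    hd_session(patient, keys$session_id[i], rows$duration_min[1],
               rows$qd_ml_min[1], plasma = pick("plasma"),
               dialysate = pick("dialysate"))
  })
}

#' Write treatment sessions to a CSV or JSON file
#'
#' Inverse of [read_sessions()]: serialises sessions to the flat one-row-
#' per-sample schema. `read_sessions(write_sessions(x, path))` reproduces
#' the sessions.
#'
#' @param sessions List of [hd_session()] objects.
#' @param path Output path; `.json` selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  rows <- do.call(rbind, lapply(sessions, function(s) {
    flat <- function(df, type)
      data.frame(patient_id = s$patient$patient_id,
                 session_id = s$session_id, sex = s$patient$sex,
                 age_y = s$patient$age_y, height_cm = s$patient$height_cm,
                 weight_pre_kg = s$patient$weight_pre_kg,
                 duration_min = s$duration_min, qd_ml_min = s$qd_ml_min,
                 sample_type = type, time_min = df$time_min,
                 conc_mmol_l = df$conc_mmol_l)
    rbind(flat(s$plasma, "plasma"), flat(s$dialysate, "dialysate"))
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' @param trajectory A `phos_trajectory` from [simulate_session()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "phos_trajectory"))
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a set of sessions
#'
#' Per session: dialyser clearance estimation, anthropometric volumes, and
#' paired model fits without and with the clearance-reduction slope. The
#' bundle assembles the per-treatment parameter table, the model-comparison
#' table (RMSE, R-squared, Fisher z), per-treatment phosphate removal
#' (simulated at the fitted parameters over the session duration), removal
#' summaries per session label and model variant, and the cohort median
#' block. Deterministic for a given `control`.
#'
#' @param sessions List of [hd_session()] objects (>= 1 valid).
#' @param control A [fit_control()].
#' @param kd_l_h Optional per-session clearances forwarded to [fit_cohort()].
#' @param out_dir Optional directory; when given, the tables are written as
#'   CSV plus a JSON metadata sidecar (`report.json`).
#' @return List of class `phos_report`: `parameters`, `comparison`,
#'   `removal` (data.frames), `removal_summaries` (list of
#'   [removal_summary()] objects keyed `<session_id>_<variant>`), `medians`,
#'   `fit_table`, `n_failures`.
#' @export
run_pipeline <- function(sessions, control = fit_control(), kd_l_h = NULL,
                         out_dir = NULL) {
  fit_table <- fit_cohort(sessions, control = control, kd_l_h = kd_l_h)
  if (length(fit_table$fits) == 0)
    stop("no session could be fitted", call. = FALSE)
  parameters <- fit_parameter_table(fit_table)
  comparison <- build_comparison_table(fit_table)

  removal <- do.call(rbind, lapply(fit_table$fits, function(f) {
    rem <- vapply(list(f$without, f$with), function(fit) {
      params <- phos_params(f$kd$kd_l_h, fit$k1, fit$k2, fit$slc,
                            dd_h = f$without$duration_min / 60)
      total_removed(simulate_session(params, f$volumes,
                                     fit$measured[1],
                                     step_min = control$step_min))
    }, numeric(1))
    data.frame(patient_id = f$patient_id, session_id = f$session_id,
               duration_min = f$without$duration_min,
               removed_without = rem[1], removed_with = rem[2])
  }))

  summaries <- list()
  for (sid in unique(removal$session_id)) {
    sub <- removal[removal$session_id == sid, ]
    if (nrow(sub) >= 2) {
      summaries[[paste0(sid, "_without")]] <-
        removal_summary(sub$removed_without,
                        label = paste(sid, "without slope"))
      summaries[[paste0(sid, "_with")]] <-
        removal_summary(sub$removed_with, label = paste(sid, "with slope"))
    }
  }

  report <- structure(
    list(parameters = parameters, comparison = comparison, removal = removal,
         removal_summaries = summaries, medians = cohort_medians(parameters),
         fit_table = fit_table, n_failures = length(fit_table$failures)),
    class = "phos_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(parameters, file.path(out_dir, "parameters.csv"),
              row.names = FALSE)
    write.csv(comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
    write.csv(removal, file.path(out_dir, "removal.csv"), row.names = FALSE)
    meta <- list(
      seed = control$seed, starts = control$starts,
      step_min = control$step_min,
      n_sessions = length(sessions), n_fitted = length(fit_table$fits),
      n_failures = length(fit_table$failures),
      medians = report$medians,
      removal_summaries = lapply(summaries, unclass))
    jsonlite::write_json(meta, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.phos_report <- function(x, ...) {
  cat(sprintf("<phos_report> %d sessions fitted (%d failures)\n",
              nrow(x$parameters), x$n_failures))
  cat(sprintf("  median slope (non-zero sessions): %.3f /h; zero-slope sessions: %d/%d\n",
              x$medians$slope_nonzero, x$medians$n_zero,
              x$medians$n_sessions))
  cat(sprintf("  with-slope RMSE below without-slope in %d/%d sessions\n",
              sum(x$comparison$rmse_with < x$comparison$rmse_without),
              nrow(x$comparison)))
  invisible(x)
}
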