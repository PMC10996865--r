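#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study conditions the model is meant for: an elderly
#' chronic haemodialysis cohort (age 71.6 +/- 10.6 y, height 160.3 +/- 8.2
#' cm, dry weight 72.2 +/- 14.2 kg, two thirds male), treatments of
#' 233 +/- 26 min with dialysate flow 446 +/- 55 mL/min, dialyser phosphate
#' clearance 8.7 +/- 1.44 L/h (145 +/- 24 mL/min), pre-dialytic plasma
#' phosphate 1.4 +/- 0.4 mmol/L, plasma sampled every 30 min plus end of
#' treatment and dialysate every 60 min plus end of treatment. Dialysate
#' noise defaults to the high intradialytic variability observed clinically
#' (CV 25.7%, dominated by machine flow regulation and pauses rather than
#' assay error); plasma noise defaults to a 2% CV, typical of clinical
#' phosphate assays. True mass-transfer coefficients are drawn log-uniform
#' over the wide ranges seen in fitted clinical data, and the true
#' clearance-reduction slope is zero with probability 0.3 (no clotting) and
#' otherwise uniform on \[0, 0.632\]/h.
#'
#' @param age_mean,age_sd,height_mean,height_sd,weight_mean,weight_sd
#'   Demographic truncated-normal parameters (years, cm, kg).
#' @param p_male Probability of a male patient.
#' @param fluid_gain_mean,fluid_gain_sd Interdialytic fluid gain added to dry
#'   weight, kg (truncated at 0).
#' @param duration_mean,duration_sd Treatment duration, minutes.
#' @param qd_mean,qd_sd Dialysate flow, mL/min.
#' @param kd_mean,kd_sd True dialyser phosphate clearance, L/h.
#' @param c0_mean,c0_sd Pre-dialytic plasma phosphate, mmol/L.
#' @param k1_range,k2_range Log-uniform ranges for the true mass-transfer
#'   coefficients, L/h.
#' @param slc_range Range of the non-zero true slope, 1/h.
#' @param slope_zero_prob Point mass at slope 0.
#' @param slope_correlation Correlation of a patient's latent slope across
#'   their sessions, in \[-1, 1\] (high by default: clotting propensity is
#'   largely a patient trait week to week).
#' @param plasma_cv,dialysate_cv Multiplicative lognormal noise CVs.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(age_mean = 71.6, age_sd = 10.6,
                          height_mean = 160.3, height_sd = 8.2,
                          weight_mean = 72.2, weight_sd = 14.2,
                          p_male = 2 / 3,
                          fluid_gain_mean = 2, fluid_gain_sd = 1,
                          duration_mean = 233, duration_sd = 26,
                          qd_mean = 446, qd_sd = 55,
                          kd_mean = 8.7, kd_sd = 1.44,
                          c0_mean = 1.4, c0_sd = 0.4,
                          k1_range = c(5, 350), k2_range = c(3, 25),
                          slc_range = c(0, 0.632),
                          slope_zero_prob = 0.3,
                          slope_correlation = 0.8,
                          plasma_cv = 0.02, dialysate_cv = 0.257) {
  cfg <- as.list(environment())
  for (nm in grep("_sd$|_cv$", names(cfg), value = TRUE))
    if (cfg[[nm]] < 0) stop("'", nm, "' must be non-negative", call. = FALSE)
  for (nm in c("p_male", "slope_zero_prob"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  if (slope_correlation < -1 || slope_correlation > 1)
    stop("'slope_correlation' must lie in [-1, 1]", call. = FALSE)
  for (nm in c("k1_range", "k2_range"))
    if (any(cfg[[nm]] <= 0) || diff(cfg[[nm]]) <= 0)
      stop("'", nm, "' must be an increasing positive range", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# Truncated-normal draw by rejection; bounds are physiologic guards, far in
# the tails for the default configurations.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

# Multiplicative lognormal noise factors with unit mean for a given CV.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Draw one virtual patient
#'
#' Demographics from truncated normals at the configured cohort means/SDs;
#' the pre-dialytic weight is the dry weight plus a non-negative fluid gain.
#'
#' @param config A [cohort_config()].
#' @param patient_id Label for the patient.
#' @param seed Optional integer; when given, the draw is deterministic and
#'   the caller's RNG state is left untouched.
#' @return An [hd_patient()] object.
#' @export
generate_patient <- function(config = cohort_config(), patient_id = "P1",
                             seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  draw <- function() {
    sex <- if (runif(1) < config$p_male) "male" else "female"
    age <- rtrunc_norm(1, config$age_mean, config$age_sd, 18, 100)
    height <- rtrunc_norm(1, config$height_mean, config$height_sd, 130, 200)
    dry <- rtrunc_norm(1, config$weight_mean, config$weight_sd, 35, 140)
    gain <- rtrunc_norm(1, config$fluid_gain_mean, config$fluid_gain_sd, 0, Inf)
    hd_patient(sex, age, height, dry + gain, patient_id = patient_id)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Draw the true kinetic parameters for one treatment
#'
#' @param config A [cohort_config()].
#' @return List with `kd`, `duration_min`, `qd_ml_min`, `c0` (k1/k2/slope are
#'   drawn at the cohort level so they can be shared/correlated within a
#'   patient).
#' @keywords internal
draw_session_truth <- function(config) {
  list(kd = rtrunc_norm(1, config$kd_mean, config$kd_sd, 1, Inf),
       duration_min = round(rtrunc_norm(1, config$duration_mean,
                                        config$duration_sd, 120, 360)),
       qd_ml_min = rtrunc_norm(1, config$qd_mean, config$qd_sd, 200, 800),
       c0 = rtrunc_norm(1, config$c0_mean, config$c0_sd, 0.4, Inf))
}

# Integration step (in minutes, an integer divisor of 1 min) keeping the
# explicit-Euler truth simulation well inside its stability bound even for
# stiff draws (large mass-transfer coefficients on a small patient). The
# fastest eigenvalue is bounded by the Gershgorin-style sum below; the step
# is chosen so lambda * dt <= 1 (stability bound 2, margin 2).
stable_step_min <- function(truth, volumes) {
  lam <- truth$k1 * (1 / volumes$V1 + 1 / volumes$V2) +
    truth$k2 * (1 / volumes$V2 + 1 / volumes$V3) +
    truth$kd * (1 + truth$slc * truth$duration_min / 120) / volumes$V1
  1 / max(1, ceiling(lam / 60))
}

# Map a uniform variate to a slope: point mass at 0, else uniform on range.
slope_from_uniform <- function(u, config) {
  p <- config$slope_zero_prob
  ifelse(u < p, 0,
         config$slc_range[1] +
           (u - p) / (1 - p) * diff(config$slc_range))
}

#' Generate one noisy treatment session from known truth
#'
#' Simulates the three-compartment model forward at 1-min resolution with
#' the true parameters, then emits plasma samples every 30 min (plus end of
#' treatment) and dialysate samples every 60 min (plus end of treatment).
#' Dialysate concentrations are built from the instantaneous outlet mass
#' balance `Cd_out(t) = f1(t) / Qd` — the only self-consistent forward model
#' for the dialysate side — and both series carry multiplicative lognormal
#' noise at the configured CVs (so a zero CV reproduces the model exactly).
#'
#' @param patient An [hd_patient()] object.
#' @param truth List with `kd`, `k1`, `k2`, `slc`, `duration_min`,
#'   `qd_ml_min`, `c0`.
#' @param config A [cohort_config()] (noise CVs are read from here).
#' @param seed Optional integer for a deterministic draw.
#' @return An [hd_session()] with the truth attached as attribute `"truth"`.
#' @export
generate_session <- function(patient, truth, config = cohort_config(),
                             seed = NULL) {
  stopifnot(inherits(patient, "hd_patient"))
  if (truth$qd_ml_min <= 0) stop("'qd_ml_min' must be positive", call. = FALSE)
  run <- function() {
    vols <- patient_volumes(patient)
    params <- phos_params(truth$kd, truth$k1, truth$k2, truth$slc,
                          dd_h = truth$duration_min / 60)
    step <- stable_step_min(truth, vols)
    traj <- simulate_session(params, vols, truth$c0, step_min = step)
    at <- function(t) round(t / step) + 1L
    dur <- truth$duration_min
    p_times <- unique(c(seq(0, dur, by = 30), dur))
    d_times <- setdiff(unique(c(seq(60, dur, by = 60), dur)), 0)
    p_true <- traj$c1[at(p_times)]
    # outlet concentration at end of treatment reflects the final minute of
    # active clearance (the gate is already closed at t = Dd exactly)
    f1_at <- traj$f1_mmol_h[at(pmin(d_times, dur - 1))]
    d_true <- f1_at / ml_min_to_l_h(truth$qd_ml_min)
    plasma <- data.frame(
      time_min = p_times,
      conc_mmol_l = p_true * lognormal_factor(length(p_true), config$plasma_cv))
    dialysate <- data.frame(
      time_min = d_times,
      conc_mmol_l = d_true * lognormal_factor(length(d_true),
                                              config$dialysate_cv))
    out <- hd_session(patient, session_id = "HD1",
                      duration_min = dur, qd_ml_min = truth$qd_ml_min,
                      plasma = plasma, dialysate = dialysate)
    attr(out, "truth") <- truth
    out
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Generate a synthetic cohort with ground truth
#'
#' Independent virtual patients, each with `sessions_per_patient` treatments.
#' Within a patient the mass-transfer coefficients k1 and k2 are shared
#' across sessions (they are patient physiology) while the
#' clearance-reduction slope is drawn per session through a Gaussian copula
#' with the configured between-session correlation (clotting propensity is a
#' patient trait, but each treatment clots on its own). All other treatment
#' parameters (kd, duration, flow, pre-dialytic phosphate) are drawn
#' independently per session.
#'
#' @param n_patients Number of patients (>= 1).
#' @param sessions_per_patient Treatments per patient (default 2).
#' @param config A [cohort_config()].
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   it.
#' @return List of class `hd_cohort`: `sessions` (list of [hd_session()],
#'   session ids `"HD1"`, `"HD2"`, ...) and `truth` (data.frame of the true
#'   per-session parameters, one row per session in the same order).
#' @export
generate_cohort <- function(n_patients = 12, sessions_per_patient = 2,
                            config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), n_patients >= 1,
            sessions_per_patient >= 1)
  rho <- config$slope_correlation
  if (rho < 0 && sessions_per_patient > 2)
    stop("negative slope correlation is only defined for 2 sessions per patient",
         call. = FALSE)
  with_local_seed(seed, {
    sessions <- list()
    truth_rows <- list()
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%02d", i)
      patient <- generate_patient(config, patient_id = pid)
      k1 <- 10^runif(1, log10(config$k1_range[1]), log10(config$k1_range[2]))
      k2 <- 10^runif(1, log10(config$k2_range[1]), log10(config$k2_range[2]))
      # latent Gaussian with pairwise correlation rho across sessions
      z <- if (rho >= 0) {
        shared <- rnorm(1)
        sqrt(rho) * shared + sqrt(1 - rho) * rnorm(sessions_per_patient)
      } else {
        e1 <- rnorm(1); e2 <- rnorm(1)
        c(e1, rho * e1 + sqrt(1 - rho^2) * e2)
      }
      slopes <- slope_from_uniform(stats::pnorm(z), config)
      for (j in seq_len(sessions_per_patient)) {
        truth <- draw_session_truth(config)
        truth$k1 <- k1; truth$k2 <- k2; truth$slc <- slopes[j]
        sess <- generate_session(patient, truth, config)
        sess$session_id <- sprintf("HD%d", j)
        sessions[[length(sessions) + 1L]] <- sess
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(patient_id = pid, session_id = sess$session_id,
                     kd = truth$kd, k1 = k1, k2 = k2, slc = slopes[j],
                     duration_min = truth$duration_min,
                     qd_ml_min = truth$qd_ml_min, c0 = truth$c0)
      }
    }
    structure(list(sessions = sessions, truth = do.call(rbind, truth_rows)),
              class = "hd_cohort")
  })
}

#' @export
print.hd_cohort <- function(x, ...) {
  cat(sprintf("<hd_cohort> %d sessions from %d patients\n",
              length(x$sessions), length(unique(x$truth$patient_id))))
  invisible(x)
}
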