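#' Kinetic model parameters
#'
#' Parameters of the three-compartment intradialytic phosphate model.
#' All rate parameters are non-negative; clearances and mass-transfer
#' coefficients are volumetric rates in L/h, the clearance-reduction slope is
#' in 1/h and the session duration in hours. The dialysis status gate s(t)
#' is 1 on the closed-open interval `[t0, t0 + Dd)` and 0 elsewhere.
#'
#' @param kd Dialyser phosphate clearance, L/h.
#' @param k1 Mass-transfer coefficient between compartments 1 and 2, L/h.
#' @param k2 Mass-transfer coefficient between compartments 2 and 3, L/h.
#' @param slc Linear slope of the clearance reduction, 1/h (default 0, i.e.
#'   constant clearance).
#' @param dd_h Dialysis duration, hours (> 0).
#' @param t0_h Dialysis start time, hours (default 0).
#' @return An object of class `phos_params`.
#' @export
#' @examples
#' phos_params(kd = 9, k1 = 40, k2 = 9, slc = 0.2, dd_h = 4)
phos_params <- function(kd, k1, k2, slc = 0, dd_h, t0_h = 0) {
  for (nm in c("kd", "k1", "k2", "slc")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(dd_h) || length(dd_h) != 1L || !is.finite(dd_h) || dd_h <= 0)
    stop("'dd_h' must be a single positive number", call. = FALSE)
  structure(list(kd = kd, k1 = k1, k2 = k2, slc = slc,
                 dd_h = dd_h, t0_h = t0_h),
            class = "phos_params")
}

#' @export
print.phos_params <- function(x, ...) {
  cat(sprintf(
    "<phos_params> kd %.2f L/h, k1 %.2f L/h, k2 %.2f L/h, slope %.3f /h, Dd %.2f h\n",
    x$kd, x$k1, x$k2, x$slc, x$dd_h))
  invisible(x)
}

#' Dialysis status gate
#'
#' 1 while dialysis runs (`t` in `[t0, t0 + Dd)`), 0 otherwise. Vectorised
#' over `t_h`.
#'
#' @param t_h Time in hours.
#' @param params A [phos_params()] object.
#' @return Numeric vector of 0/1.
#' @export
dialysis_status <- function(t_h, params) {
  stopifnot(inherits(params, "phos_params"))
  as.numeric(t_h >= params$t0_h & t_h < params$t0_h + params$dd_h)
}

#' Linear clearance-reduction factor
#'
#' Dimensionless modulation of the dialyser clearance,
#' `1 - SLc * ((t - t0) - Dd/2)`, centred at mid-treatment so its time
#' average over the session equals 1 for any slope (as long as no clamping
#' occurs): the slope redistributes clearance within the treatment without
#' changing its mean. Whenever `SLc * ((t - t0) - Dd/2) > 1` the factor is
#' clamped to 0 so the effective clearance never turns negative.
#'
#' For a slope of 0.2/h over a 4 h session the factor runs 1.40, 1.20, 1.00,
#' 0.80, 0.60 at the 0, 1, 2, 3 and 4 h marks.
#'
#' @param t_h Time in hours; vectorised. Must lie within `[t0, t0 + Dd]`.
#' @param params A [phos_params()] object.
#' @return Non-negative dimensionless factor(s).
#' @export
#' @examples
#' p <- phos_params(kd = 9, k1 = 40, k2 = 9, slc = 0.2, dd_h = 4)
#' clearance_adjustment(0:4, p)  # 1.4 1.2 1.0 0.8 0.6
clearance_adjustment <- function(t_h, params) {
  stopifnot(inherits(params, "phos_params"))
  if (any(t_h < params$t0_h - 1e-12 | t_h > params$t0_h + params$dd_h + 1e-12))
    stop("'t_h' outside the dialysis session [t0, t0 + Dd]", call. = FALSE)
  raw <- params$slc * ((t_h - params$t0_h) - params$dd_h / 2)
  ifelse(raw > 1, 0, 1 - raw)
}

#' Dialytic phosphate flux
#'
#' Phosphate eliminated through the dialyser at time `t`:
#' `f1 = kd * (C1 - Cd) * clearance_adjustment(t) * s(t)` in mmol/h.
#' The flux is zero whenever the dialysis gate `s` is 0.
#'
#' @param c1 Plasma (compartment 1) phosphate concentration, mmol/L.
#' @param cd Dialysate-side phosphate concentration, mmol/L (0 for fresh
#'   dialysate).
#' @param t_h Time in hours.
#' @param params A [phos_params()] object.
#' @param s Optional explicit dialysis status (0 or 1); by default derived
#'   from `t_h` via [dialysis_status()].
#' @return Flux in mmol/h.
#' @export
#' @examples
#' p <- phos_params(kd = 9, k1 = 0, k2 = 0, slc = 0, dd_h = 4)
#' dialytic_flux(1.5, 0, 0, p)  # 13.5 mmol/h
dialytic_flux <- function(c1, cd, t_h, params, s = NULL) {
  stopifnot(inherits(params, "phos_params"))
  if (any(c1 < 0) || any(cd < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (is.null(s)) s <- dialysis_status(t_h, params)
  # evaluate the adjustment without the session-range check: wherever the
  # gate is 0 the flux is 0 regardless of the factor
  raw <- params$slc * ((t_h - params$t0_h) - params$dd_h / 2)
  adj <- ifelse(raw > 1, 0, 1 - raw)
  params$kd * (c1 - cd) * adj * s
}

#' Simulate one dialysis session
#'
#' Integrates the three-compartment system with fixed-step explicit Euler
#' (default step 1 min). Masses evolve as
#' `dM1/dt = k1 (C2 - C1) - f1`, `dM2/dt = k2 (C3 - C2) - k1 (C2 - C1)`,
#' `dM3/dt = -k2 (C3 - C2)` with `Ci = Mi / Vi` and constant volumes
#' (ultrafiltration ignored). All three compartments start at the
#' pre-dialytic plasma concentration (inter-compartment equilibrium), so the
#' pre-dialytic sample fully determines the initial state. Cumulative removal
#' accumulates `f1` on the same grid, so the discrete mass balance
#' `removed(T) + M1(T) + M2(T) + M3(T) = M1(0) + M2(0) + M3(0)` holds at
#' machine precision.
#'
#' @param params A [phos_params()] object.
#' @param volumes An `hd_volumes` object (see [partition_volumes()]).
#' @param c1_init Pre-dialytic plasma phosphate concentration, mmol/L.
#' @param dialysate Optional dialysate-side concentration profile: a
#'   data.frame with columns `time_min` and `conc_mmol_l`, applied
#'   stepwise-constant (last observation carried forward). Default: fresh
#'   dialysate, `Cd(t) = 0`.
#' @param step_min Integration step in minutes (default 1).
#' @return A `phos_trajectory`: a data.frame with columns `time_min`, `c1`,
#'   `c2`, `c3` (mmol/L), `f1_mmol_h` and `removed_mmol`, carrying the
#'   parameters and volumes as attributes.
#' @export
#' @examples
#' vols <- partition_volumes(36)
#' p <- phos_params(kd = 9, k1 = 40, k2 = 9, slc = 0.2, dd_h = 4)
#' traj <- simulate_session(p, vols, c1_init = 1.5)
#' total_removed(traj)
simulate_session <- function(params, volumes, c1_init, dialysate = NULL,
                             step_min = 1) {
  stopifnot(inherits(params, "phos_params"), inherits(volumes, "hd_volumes"))
  if (!is.numeric(c1_init) || length(c1_init) != 1L || c1_init < 0)
    stop("'c1_init' must be a single non-negative concentration", call. = FALSE)
  if (step_min <= 0) stop("'step_min' must be positive", call. = FALSE)
  if (volumes$V1 <= 0 && params$kd > 0)
    stop("singular model: zero plasma-water volume with non-zero clearance",
         call. = FALSE)
  if (is.null(dialysate)) {
    cd_t <- numeric(0); cd_v <- numeric(0)
  } else {
    stopifnot(is.data.frame(dialysate),
              all(c("time_min", "conc_mmol_l") %in% names(dialysate)))
    ord <- order(dialysate$time_min)
    cd_t <- params$t0_h + dialysate$time_min[ord] / 60
    cd_v <- dialysate$conc_mmol_l[ord]
  }
  sim <- euler_core(c1_init, volumes$V1, volumes$V2, volumes$V3,
                    params$kd, params$k1, params$k2, params$slc,
                    params$dd_h, params$t0_h, step_min / 60, cd_t, cd_v)
  out <- data.frame(time_min = round((sim$time_h - params$t0_h) * 60, 10),
                    c1 = sim$c1, c2 = sim$c2, c3 = sim$c3,
                    f1_mmol_h = sim$f1_mmol_h,
                    removed_mmol = sim$removed_mmol)
  attr(out, "params") <- params
  attr(out, "volumes") <- volumes
  attr(out, "c1_init") <- c1_init
  attr(out, "step_min") <- step_min
  class(out) <- c("phos_trajectory", "data.frame")
  out
}

#' Total phosphate removed over a session
#'
#' Cumulative dialytic removal at end of session, in mmol. By discrete mass
#' conservation this equals the total compartment mass lost between start
#' and end.
#'
#' @param trajectory A `phos_trajectory` from [simulate_session()].
#' @return Removed phosphate in mmol.
#' @export
total_removed <- function(trajectory) {
  stopifnot(inherits(trajectory, "phos_trajectory"))
  if (nrow(trajectory) == 0) stop("empty trajectory", call. = FALSE)
  trajectory$removed_mmol[nrow(trajectory)]
}

#' @export
print.phos_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<phos_trajectory> %d points over %.0f min (step %.2g min), removed %.2f mmol\n",
    nrow(x), x$time_min[nrow(x)], attr(x, "step_min"), total_removed(x)))
  invisible(x)
}
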