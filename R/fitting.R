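#' Root mean square error
#'
#' @param modelled,measured Equal-length numeric series (mmol/L).
#' @return `sqrt(mean((modelled - measured)^2))`.
#' @export
#' @examples
#' rmse(c(1, 2), c(2, 4))  # sqrt(2.5)
rmse <- function(modelled, measured) {
  if (length(modelled) == 0 || length(modelled) != length(measured))
    stop("'modelled' and 'measured' must be non-empty and of equal length",
         call. = FALSE)
  sqrt(mean((modelled - measured)^2))
}

#' Optimiser settings for treatment fitting
#'
#' The fit is a bounded multi-start local search: `starts` Latin-hypercube
#' start points (log-spaced in k1 and k2, linear in the slope) are each
#' polished with a box-constrained quasi-Newton run (PORT, via
#' [stats::nlminb()]); the best solution is kept, with ties broken by lowest
#' RMSE, then lowest slope, then lowest k1. Upper bounds are wide soft caps:
#' fitted mass-transfer coefficients in clinical data can reach several
#' hundred L/h.
#'
#' @param starts Number of multi-start points (default 20).
#' @param seed Integer seed making the start draw (and hence the whole fit)
#'   deterministic.
#' @param step_min Integration step of the embedded simulation, minutes.
#' @param k_upper Upper bound for k1 and k2, L/h.
#' @param sl_upper Upper bound for the clearance-reduction slope, 1/h.
#' @param max_eval Objective-evaluation cap per start.
#' @return List of class `fit_control`.
#' @export
fit_control <- function(starts = 20, seed = 1234L, step_min = 1,
                        k_upper = 1000, sl_upper = 2, max_eval = 2000) {
  stopifnot(starts >= 1, is.numeric(seed), step_min > 0,
            k_upper > 0, sl_upper > 0, max_eval > 1)
  structure(list(starts = as.integer(starts), seed = as.integer(seed),
                 step_min = step_min, k_upper = k_upper,
                 sl_upper = sl_upper, max_eval = as.integer(max_eval)),
            class = "fit_control")
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Modelled plasma concentration at the plasma sampling times: thin wrapper
# around the compiled Euler core, used thousands of times per fit.
modelled_c1_at <- function(times_min, kd, k1, k2, slc, dd_h, c1_init,
                           volumes, step_min) {
  sim <- euler_core(c1_init, volumes$V1, volumes$V2, volumes$V3,
                    kd, k1, k2, slc, dd_h, 0, step_min / 60,
                    numeric(0), numeric(0))
  idx <- pmin(round(times_min / step_min), length(sim$c1) - 1L) + 1L
  sim$c1[idx]
}

#' Fit mass-transfer coefficients and the clearance-reduction slope
#'
#' Estimates `k1`, `k2` and (optionally) the linear clearance-reduction slope
#' for one treatment by minimising the RMSE between the modelled and measured
#' plasma phosphate concentrations at the plasma sampling times. All fitted
#' parameters are constrained non-negative. The pre-dialytic sample sets the
#' initial condition (all compartments in equilibrium at that concentration)
#' and is also included as a fitted time point; its residual is zero by
#' construction. When `with_slope = FALSE` the slope is fixed at 0.
#'
#' @param session An [hd_session()] object with at least 4 intradialytic
#'   plasma samples plus the pre-dialytic one.
#' @param kd_l_h Dialyser phosphate clearance for this treatment, L/h
#'   (typically from [session_kd()]).
#' @param volumes `hd_volumes` for this patient.
#' @param with_slope Fit the slope (`TRUE`) or fix it at 0 (`FALSE`).
#' @param control A [fit_control()] object.
#' @param extra_starts Optional list of numeric `c(k1, k2, slc)` vectors
#'   appended to the multi-start set (used by [fit_cohort()] to seed the
#'   with-slope search with the without-slope optimum, which makes the
#'   nested-model inequality `RMSE_with <= RMSE_without` exact).
#' @return A list of class `phos_fit`: `k1`, `k2`, `slc`, `with_slope`,
#'   `rmse`, `n_samples`, `converged`, `n_starts_used`,
#'   `objective_evaluations`, plus the fitted series (`times_min`,
#'   `measured`, `modelled`) and the inputs (`kd_l_h`, `volumes`,
#'   `duration_min`, `session_id`, `patient_id`).
#' @export
fit_treatment <- function(session, kd_l_h, volumes, with_slope = TRUE,
                          control = fit_control(), extra_starts = NULL) {
  stopifnot(inherits(session, "hd_session"), inherits(volumes, "hd_volumes"),
            inherits(control, "fit_control"))
  plasma <- session$plasma
  if (nrow(plasma) < 5)
    stop("need the pre-dialytic sample plus at least 4 intradialytic samples",
         call. = FALSE)
  times <- plasma$time_min
  measured <- plasma$conc_mmol_l
  c1_init <- measured[1]
  dd_h <- session$duration_min / 60
  n_eval <- 0L

  # parameter combinations beyond the explicit-Euler stability bound (very
  # large k on the 1-min grid) abort the integration; they get a flat
  # penalty far above any attainable RMSE so the search moves away
  penalty <- 1e3
  objective <- function(par) {
    n_eval <<- n_eval + 1L
    mod <- tryCatch(
      modelled_c1_at(times, kd_l_h, par[1], par[2],
                     if (with_slope) par[3] else 0,
                     dd_h, c1_init, volumes, control$step_min),
      error = function(e) NULL)
    if (is.null(mod) || anyNA(mod) || any(!is.finite(mod))) return(penalty)
    sqrt(mean((mod - measured)^2))
  }

  npar <- if (with_slope) 3L else 2L
  lower <- rep(0, npar)
  upper <- c(control$k_upper, control$k_upper,
             if (with_slope) control$sl_upper)
  # deterministic Latin-hypercube start points: log-spaced k1, k2 on
  # [0.5, 500] L/h, linear slope on [0, 0.8]/h
  grid <- with_local_seed(control$seed, lhs::randomLHS(control$starts, 3L))
  starts <- cbind(10^(log10(0.5) + grid[, 1] * (log10(500) - log10(0.5))),
                  10^(log10(0.5) + grid[, 2] * (log10(500) - log10(0.5))),
                  grid[, 3] * 0.8)
  start_list <- lapply(seq_len(nrow(starts)), function(i) starts[i, 1:npar])
  for (es in extra_starts) {
    es <- pmin(pmax(es[1:npar], lower), upper)
    start_list <- c(start_list, list(es))
  }

  runs <- lapply(start_list, function(s0) {
    fit <- stats::nlminb(s0, objective, lower = lower, upper = upper,
                         control = list(eval.max = control$max_eval,
                                        iter.max = control$max_eval))
    list(par = fit$par, value = fit$objective,
         converged = fit$convergence == 0)
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  slcs <- vapply(runs, function(r) if (with_slope) r$par[3] else 0, numeric(1))
  k1s <- vapply(runs, function(r) r$par[1], numeric(1))
  best <- runs[[order(vals, slcs, k1s)[1]]]

  modelled <- modelled_c1_at(times, kd_l_h, best$par[1], best$par[2],
                             if (with_slope) best$par[3] else 0,
                             dd_h, c1_init, volumes, control$step_min)
  structure(
    list(k1 = best$par[1], k2 = best$par[2],
         slc = if (with_slope) best$par[3] else 0,
         with_slope = with_slope, rmse = best$value,
         n_samples = length(times),
         converged = any(vapply(runs, `[[`, logical(1), "converged")),
         n_starts_used = length(start_list),
         objective_evaluations = n_eval,
         times_min = times, measured = measured, modelled = modelled,
         kd_l_h = kd_l_h, volumes = volumes,
         duration_min = session$duration_min,
         session_id = session$session_id,
         patient_id = session$patient$patient_id),
    class = "phos_fit"
  )
}

#' @export
print.phos_fit <- function(x, ...) {
  cat(sprintf(
    "<phos_fit %s/%s %s> k1 %.2f, k2 %.2f L/h, slope %.3f /h, RMSE %.4f mmol/L (n = %d)\n",
    x$patient_id, x$session_id,
    if (x$with_slope) "with slope" else "no slope",
    x$k1, x$k2, x$slc, x$rmse, x$n_samples))
  invisible(x)
}

#' Fit a cohort of treatments, with and without the slope
#'
#' For each session: estimates the dialyser clearance with [session_kd()],
#' derives the distribution volumes from the patient's anthropometry, then
#' fits the model without the slope and with the slope. The without-slope
#' optimum is passed to the with-slope search as an extra start point, so
#' `RMSE_with <= RMSE_without` holds exactly on every pair. Per-session
#' failures are recorded, not raised.
#'
#' @param sessions List of [hd_session()] objects.
#' @param control A [fit_control()] object.
#' @param kd_l_h Optional numeric vector of per-session clearances (L/h),
#'   bypassing [session_kd()] (useful when dialysate series are synthetic or
#'   absent).
#' @return List of class `phos_fit_table`: `fits` (one element per fitted
#'   session, each with `without` and `with` `phos_fit`s plus `kd` report and
#'   `volumes`) and `failures` (list of `session_id`/message pairs).
#' @export
fit_cohort <- function(sessions, control = fit_control(), kd_l_h = NULL) {
  if (length(sessions) == 0) stop("empty cohort", call. = FALSE)
  if (!is.null(kd_l_h)) stopifnot(length(kd_l_h) == length(sessions))
  fits <- list()
  failures <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    res <- tryCatch({
      kd_rep <- if (is.null(kd_l_h)) session_kd(s)
                else list(kd_l_h = kd_l_h[i])
      vols <- patient_volumes(s$patient)
      fit_wo <- fit_treatment(s, kd_rep$kd_l_h, vols, with_slope = FALSE,
                              control = control)
      fit_w <- fit_treatment(s, kd_rep$kd_l_h, vols, with_slope = TRUE,
                             control = control,
                             extra_starts = list(c(fit_wo$k1, fit_wo$k2, 0)))
      list(patient_id = s$patient$patient_id, session_id = s$session_id,
           kd = kd_rep, volumes = vols, without = fit_wo, with = fit_w)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(patient_id = s$patient$patient_id, session_id = s$session_id,
             message = conditionMessage(res))
    } else {
      fits[[length(fits) + 1L]] <- res
    }
  }
  structure(list(fits = fits, failures = failures), class = "phos_fit_table")
}

#' @export
print.phos_fit_table <- function(x, ...) {
  cat(sprintf("<phos_fit_table> %d fitted sessions, %d failures\n",
              length(x$fits), length(x$failures)))
  invisible(x)
}

#' Parameter table of a fitted cohort
#'
#' One row per fitted session with the with-slope parameters and the shared
#' volumes and clearance — the per-treatment parameter summary used for
#' cohort medians.
#'
#' @param fit_table A `phos_fit_table` from [fit_cohort()].
#' @return data.frame with columns `patient_id`, `session_id`, `slope`,
#'   `V1`, `V2`, `V3`, `kd`, `k1`, `k2`.
#' @export
fit_parameter_table <- function(fit_table) {
  stopifnot(inherits(fit_table, "phos_fit_table"))
  do.call(rbind, lapply(fit_table$fits, function(f) {
    data.frame(patient_id = f$patient_id, session_id = f$session_id,
               slope = f$with$slc, V1 = f$volumes$V1, V2 = f$volumes$V2,
               V3 = f$volumes$V3, kd = f$kd$kd_l_h, k1 = f$with$k1,
               k2 = f$with$k2)
  }))
}
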