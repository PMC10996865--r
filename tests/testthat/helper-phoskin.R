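# Shared fixtures, all built in code.

# Single-pool limit: no inter-compartment exchange, fresh dialysate, so
# C1(t) = C1(0) exp(-kd t / V1) in closed form.
single_pool_volumes <- function(v1 = 3) {
  structure(list(V1 = v1, V2 = 0, V3 = 0), class = "hd_volumes")
}

# Noise-free generator configuration with a fixed non-zero slope range.
noiseless_config <- function(...) {
  cohort_config(plasma_cv = 0, dialysate_cv = 0, ...)
}

# One deterministic noiseless session with fully known truth.
make_known_session <- function(slc = 0.2, kd = 9, k1 = 40, k2 = 9,
                               duration_min = 240, c0 = 1.5, seed = 7,
                               plasma_cv = 0, dialysate_cv = 0) {
  cfg <- cohort_config(plasma_cv = plasma_cv, dialysate_cv = dialysate_cv)
  patient <- generate_patient(cfg, seed = seed)
  truth <- list(kd = kd, k1 = k1, k2 = k2, slc = slc,
                duration_min = duration_min, qd_ml_min = 450, c0 = c0)
  list(session = generate_session(patient, truth, cfg, seed = seed + 1),
       truth = truth, patient = patient,
       volumes = patient_volumes(patient))
}
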