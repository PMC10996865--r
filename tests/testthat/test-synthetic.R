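test_that("generation is a deterministic function of the seed", {
  cfg <- cohort_config()
  p1 <- generate_patient(cfg, seed = 9)
  p2 <- generate_patient(cfg, seed = 9)
  expect_identical(p1, p2)
  c1 <- generate_cohort(3, 2, cfg, seed = 4)
  c2 <- generate_cohort(3, 2, cfg, seed = 4)
  expect_identical(c1, c2)
  c3 <- generate_cohort(3, 2, cfg, seed = 5)
  expect_false(identical(c1$truth, c3$truth))
})

test_that("cohort structure mirrors the study layout", {
  coh <- generate_cohort(12, 2, cohort_config(), seed = 2)
  expect_length(coh$sessions, 24)
  expect_equal(nrow(coh$truth), 24)
  expect_equal(unique(coh$truth$session_id), c("HD1", "HD2"))
  # a 240-min session samples plasma at 0, 30, ..., 240: nine samples
  fx <- make_known_session(duration_min = 240)
  expect_equal(nrow(fx$session$plasma), 9)
  expect_equal(fx$session$plasma$time_min, seq(0, 240, by = 30))
  expect_equal(fx$session$dialysate$time_min, seq(60, 240, by = 60))
  # non-multiple durations append the end-of-treatment sample
  fx233 <- make_known_session(duration_min = 233)
  expect_equal(max(fx233$session$plasma$time_min), 233)
  expect_equal(max(fx233$session$dialysate$time_min), 233)
})

test_that("zero noise reproduces the forward model exactly", {
  fx <- make_known_session(slc = 0.25)
  params <- phos_params(fx$truth$kd, fx$truth$k1, fx$truth$k2, fx$truth$slc,
                        dd_h = fx$truth$duration_min / 60)
  traj <- simulate_session(params, fx$volumes, fx$truth$c0)
  expect_equal(fx$session$plasma$conc_mmol_l,
               traj$c1[match(fx$session$plasma$time_min, traj$time_min)],
               tolerance = 1e-12)
  # dialysate from outlet mass balance is positive and below paired plasma
  expect_true(all(fx$session$dialysate$conc_mmol_l > 0))
  paired <- traj$c1[match(fx$session$dialysate$time_min, traj$time_min)]
  expect_true(all(fx$session$dialysate$conc_mmol_l < paired *
                    (fx$truth$kd * 1.7) / (fx$truth$qd_ml_min * 0.06)))
})

test_that("patient draws match the cohort demographics", {
  cfg <- cohort_config()
  set.seed(100)
  pats <- replicate(10000, {
    p <- generate_patient(cfg)
    c(age = p$age_y, male = p$sex == "male", h = p$height_cm)
  })
  expect_lt(abs(mean(pats["age", ]) - 71.6), 0.5)
  expect_lt(abs(mean(pats["male", ]) - 2 / 3), 0.02)
  expect_lt(abs(mean(pats["h", ]) - 160.3), 0.5)
  expect_error(cohort_config(age_sd = -1), "non-negative")
  expect_error(cohort_config(slope_correlation = 1.5), "-1, 1")
})

test_that("between-session slope correlation is controlled by the copula", {
  # perfect correlation: each patient's two true slopes coincide
  c1 <- generate_cohort(20, 2, cohort_config(slope_correlation = 1), seed = 8)
  s1 <- c1$truth$slc[c1$truth$session_id == "HD1"]
  s2 <- c1$truth$slc[c1$truth$session_id == "HD2"]
  expect_equal(s1, s2, tolerance = 1e-12)
  # independence: concordance of true slopes collapses
  c0 <- generate_cohort(200, 2, cohort_config(slope_correlation = 0), seed = 8)
  t1 <- c0$truth$slc[c0$truth$session_id == "HD1"]
  t2 <- c0$truth$slc[c0$truth$session_id == "HD2"]
  expect_lt(slope_correlation(t1, t2), 0.05)
})

test_that("fitted slopes inherit the generated concordance end to end", {
  cfg <- cohort_config(slope_correlation = 1, plasma_cv = 0, dialysate_cv = 0,
                       slope_zero_prob = 0.3)
  coh <- generate_cohort(6, 2, cfg, seed = 14)
  fitted <- vapply(seq_along(coh$sessions), function(i) {
    fit_treatment(coh$sessions[[i]], coh$truth$kd[i],
                  patient_volumes(coh$sessions[[i]]$patient),
                  with_slope = TRUE, control = fit_control(starts = 8))$slc
  }, numeric(1))
  f1 <- fitted[coh$truth$session_id == "HD1"]
  f2 <- fitted[coh$truth$session_id == "HD2"]
  expect_gt(slope_correlation(f1, f2), 0.95)
})
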