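test_that("dialysate filter drops sub-threshold and unmeasurable samples in order", {
  d <- data.frame(time_min = c(60, 120, 180), conc_mmol_l = c(0.05, 0.30, 0.25))
  f <- filter_dialysate(d)
  expect_equal(f$conc_mmol_l, c(0.30, 0.25))
  expect_equal(attr(f, "dropped_outliers"), 1)
  expect_equal(attr(f, "dropped_unmeasurable"), 0)

  ok <- data.frame(time_min = c(60, 120), conc_mmol_l = c(0.30, 0.25))
  expect_equal(filter_dialysate(ok)$conc_mmol_l, c(0.30, 0.25))

  low <- data.frame(time_min = c(60, 120), conc_mmol_l = c(0.02, 0.05))
  expect_warning(f2 <- filter_dialysate(low), "all dialysate samples")
  expect_equal(nrow(f2), 0)
  expect_equal(attr(f2, "dropped_outliers"), 2)

  na <- data.frame(time_min = c(60, 120), conc_mmol_l = c(NA, 0.3))
  f3 <- filter_dialysate(na)
  expect_equal(attr(f3, "dropped_unmeasurable"), 1)
  expect_equal(f3$conc_mmol_l, 0.3)
})

test_that("kd ratio estimator reproduces hand arithmetic", {
  d <- data.frame(time_min = c(60, 120, 180), conc_mmol_l = c(0.30, 0.25, 0.20))
  p <- data.frame(time_min = c(60, 120, 180), conc_mmol_l = c(1.2, 1.0, 0.8))
  expect_equal(estimate_kd(d, p, 27)$kd_l_h, 6.75)
  # constant series closed form d*Q/p
  dc <- data.frame(time_min = c(60, 120), conc_mmol_l = c(0.3, 0.3))
  pc <- data.frame(time_min = c(60, 120), conc_mmol_l = c(1.5, 1.5))
  expect_equal(estimate_kd(dc, pc, 30)$kd_l_h, 0.3 * 30 / 1.5)
  # filter-then-ratio: the 0.05 outlier goes before the ratio
  d2 <- data.frame(time_min = c(60, 120), conc_mmol_l = c(0.05, 0.30))
  p2 <- data.frame(time_min = c(60, 120), conc_mmol_l = c(1.0, 1.0))
  expect_equal(estimate_kd(filter_dialysate(d2), p2, 27)$kd_l_h, 8.1)
})

test_that("kd is linear in flow and invariant to sample order", {
  d <- data.frame(time_min = c(60, 120, 180), conc_mmol_l = c(0.31, 0.24, 0.19))
  p <- data.frame(time_min = c(60, 120, 180), conc_mmol_l = c(1.3, 1.05, 0.9))
  k1 <- estimate_kd(d, p, 20)$kd_l_h
  k2 <- estimate_kd(d, p, 40)$kd_l_h
  expect_equal(k2, 2 * k1)
  perm <- c(3, 1, 2)
  expect_equal(estimate_kd(d[perm, ], p[perm, ], 20)$kd_l_h, k1)
})

test_that("pairing uses the nearest plasma sample within 5 min, else excludes", {
  d <- data.frame(time_min = c(62, 150), conc_mmol_l = c(0.30, 0.25))
  p <- data.frame(time_min = c(60, 120), conc_mmol_l = c(1.2, 1.0))
  est <- estimate_kd(d, p, 27)
  # 62 pairs with 60; 150 has no partner within 5 min and is dropped entirely
  expect_equal(est$n_d, 1)
  expect_equal(est$kd_l_h, 0.30 * 27 / 1.2)
  far <- data.frame(time_min = 90, conc_mmol_l = 0.3)
  expect_error(estimate_kd(far, p, 27), "pairing tolerance")
})

test_that("estimation errors are raised for empty or degenerate series", {
  p <- data.frame(time_min = 60, conc_mmol_l = 1)
  empty <- data.frame(time_min = numeric(0), conc_mmol_l = numeric(0))
  expect_error(estimate_kd(empty, p, 27), "empty dialysate")
  d <- data.frame(time_min = 60, conc_mmol_l = 0.3)
  expect_error(estimate_kd(d, empty, 27), "plasma")
  p0 <- data.frame(time_min = 60, conc_mmol_l = 0)
  expect_error(estimate_kd(d, p0, 27), "zero")
  expect_error(estimate_kd(d, p, -1), "positive")
})

test_that("noiseless synthetic sessions recover the true clearance to within 2%", {
  cfg <- noiseless_config(slc_range = c(0, 0), slope_zero_prob = 1)
  coh <- generate_cohort(6, 1, cfg, seed = 31)
  for (i in seq_along(coh$sessions)) {
    est <- session_kd(coh$sessions[[i]])
    expect_lt(abs(est$kd_l_h - coh$truth$kd[i]) / coh$truth$kd[i], 0.02)
  }
})

test_that("estimates under study-default settings land in the clinical range", {
  cfg <- noiseless_config(slope_zero_prob = 1, slc_range = c(0, 0))
  coh <- generate_cohort(8, 1, cfg, seed = 13)
  kds <- vapply(coh$sessions, function(s) session_kd(s)$kd_l_h, numeric(1))
  expect_true(all(kds > 6 & kds < 12))
})
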