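test_that("clearance-reduction factor runs 140%..60% over a 4 h session at slope 0.2/h", {
  p <- phos_params(kd = 9, k1 = 40, k2 = 9, slc = 0.2, dd_h = 4)
  expect_equal(clearance_adjustment(0:4, p), c(1.40, 1.20, 1.00, 0.80, 0.60))
})

test_that("clearance-reduction factor is clamped at zero and unit for zero slope", {
  p0 <- phos_params(kd = 9, k1 = 40, k2 = 9, slc = 0, dd_h = 4)
  expect_equal(clearance_adjustment(seq(0, 4, by = 0.5), p0), rep(1, 9))
  psteep <- phos_params(kd = 9, k1 = 40, k2 = 9, slc = 0.632, dd_h = 4)
  expect_equal(clearance_adjustment(4, psteep), 0)  # raw -0.264 clamped
  expect_gt(clearance_adjustment(0, psteep), 1)
  expect_error(clearance_adjustment(5, p0), "outside")
  # non-negativity across slopes and times
  for (slc in c(0, 0.3, 0.632, 1.5)) {
    p <- phos_params(9, 40, 9, slc, dd_h = 4)
    expect_true(all(clearance_adjustment(seq(0, 4, by = 0.01), p) >= 0))
  }
})

test_that("time-averaged clearance factor equals 1 whenever no clamping occurs", {
  for (slc in c(0, 0.1, 0.25, 0.49)) {
    p <- phos_params(9, 40, 9, slc, dd_h = 4)  # slc * Dd/2 <= 1: unclamped
    avg <- stats::integrate(function(t) clearance_adjustment(t, p),
                            0, 4)$value / 4
    expect_equal(avg, 1, tolerance = 1e-9)
  }
})

test_that("dialytic flux is gated by dialysis status and scaled by the factor", {
  p <- phos_params(kd = 9, k1 = 0, k2 = 0, slc = 0, dd_h = 4)
  expect_equal(dialytic_flux(1.5, 0, 0, p), 13.5)
  expect_equal(dialytic_flux(1.5, 0, 5, p), 0)      # after the session
  expect_equal(dialytic_flux(1.5, 0, 1, p, s = 0), 0)  # explicit gate off
  ps <- phos_params(kd = 9, k1 = 0, k2 = 0, slc = 0.2, dd_h = 4)
  expect_equal(dialytic_flux(1.5, 0, 0, ps), 13.5 * 1.4)
  expect_error(dialytic_flux(-1, 0, 0, p), "non-negative")
})

test_that("single-pool limit matches the closed-form exponential", {
  p <- phos_params(kd = 3, k1 = 0, k2 = 0, slc = 0, dd_h = 1)
  v <- single_pool_volumes(3)
  tr1 <- simulate_session(p, v, 1.5, step_min = 1)
  exact <- 1.5 * exp(-1)
  expect_lt(abs(tr1$c1[61] - exact) / exact, 0.01)
  expect_lt(abs(total_removed(tr1) - 4.5 * (1 - exp(-1))) /
              (4.5 * (1 - exp(-1))), 0.01)
  # error shrinks by an order of magnitude with a 0.1-min step
  tr01 <- simulate_session(p, v, 1.5, step_min = 0.1)
  expect_lt(abs(tr01$c1[601] - exact) / exact, 0.001)
})

test_that("kd = 0 with equilibrated start leaves C1 constant and removes nothing", {
  p <- phos_params(kd = 0, k1 = 40, k2 = 9, slc = 0, dd_h = 4)
  tr <- simulate_session(p, partition_volumes(36), 1.5)
  expect_equal(tr$c1, rep(1.5, nrow(tr)), tolerance = 1e-12)
  expect_equal(total_removed(tr), 0)
})

test_that("discrete mass balance closes to 1e-9 for random parameter draws", {
  set.seed(42)
  for (i in 1:20) {
    vols <- partition_volumes(runif(1, 25, 50))
    p <- phos_params(kd = runif(1, 5, 12), k1 = runif(1, 5, 80),
                     k2 = runif(1, 3, 25), slc = runif(1, 0, 0.632),
                     dd_h = runif(1, 3, 4.5))
    c0 <- runif(1, 0.8, 2.5)
    tr <- simulate_session(p, vols, c0)
    m0 <- c0 * (vols$V1 + vols$V2 + vols$V3)
    n <- nrow(tr)
    mT <- tr$c1[n] * vols$V1 + tr$c2[n] * vols$V2 + tr$c3[n] * vols$V3
    expect_lt(abs(total_removed(tr) + mT - m0) / m0, 1e-9)
    # trajectory invariants
    expect_true(all(abs(diff(tr$time_min) - 1) < 1e-9))
    expect_true(all(diff(tr$removed_mmol) >= -1e-12))
    expect_equal(total_removed(tr), m0 - mT, tolerance = 1e-9)
  }
})

test_that("Euler trajectory converges to a high-order adaptive reference", {
  vols <- partition_volumes(42.3)
  p <- phos_params(kd = 8.88, k1 = 44.89, k2 = 8.76, slc = 0.18, dd_h = 4)
  rhs <- function(t, y, parms) {
    C1 <- y[1] / vols$V1; C2 <- y[2] / vols$V2; C3 <- y[3] / vols$V3
    raw <- p$slc * (t - p$dd_h / 2)
    f1 <- p$kd * C1 * (if (raw > 1) 0 else 1 - raw)
    list(c(p$k1 * (C2 - C1) - f1,
           p$k2 * (C3 - C2) - p$k1 * (C2 - C1),
           -p$k2 * (C3 - C2)))
  }
  y0 <- 1.4 * c(vols$V1, vols$V2, vols$V3)
  dev_at <- function(step_min) {
    tr <- simulate_session(p, vols, 1.4, step_min = step_min)
    ref <- deSolve::lsoda(y0, tr$time_min / 60, rhs, NULL,
                          rtol = 1e-10, atol = 1e-12)
    max(abs(tr$c1 - ref[, 2] / vols$V1) / (ref[, 2] / vols$V1))
  }
  d1 <- dev_at(1)
  d01 <- dev_at(0.1)
  expect_lt(d1, 0.02)       # first-order error at the default 1-min step
  expect_lt(d01, 0.002)     # shrinks linearly with the step
  expect_lt(d01, d1 / 5)
})

test_that("a supplied dialysate profile slows elimination", {
  vols <- partition_volumes(36)
  p <- phos_params(kd = 9, k1 = 40, k2 = 9, slc = 0, dd_h = 4)
  cd <- data.frame(time_min = c(0, 120), conc_mmol_l = c(0.3, 0.2))
  tr0 <- simulate_session(p, vols, 1.5)
  trd <- simulate_session(p, vols, 1.5, dialysate = cd)
  expect_gt(total_removed(tr0), total_removed(trd))
  expect_true(all(trd$c1 >= tr0$c1 - 1e-12))
})

test_that("degenerate inputs raise the documented errors", {
  p <- phos_params(kd = 9, k1 = 0, k2 = 0, slc = 0, dd_h = 4)
  expect_error(simulate_session(p, single_pool_volumes(0), 1.5), "singular")
  expect_error(phos_params(kd = -1, k1 = 0, k2 = 0, dd_h = 4), "non-negative")
  expect_error(phos_params(kd = 1, k1 = 0, k2 = 0, dd_h = 0), "positive")
  tr <- simulate_session(p, single_pool_volumes(3), 1.5)
  expect_error(total_removed(structure(tr[0, ],
                                       class = c("phos_trajectory", "data.frame"))),
               "empty")
})
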