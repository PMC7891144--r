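sine_traj <- function(peak_at = 6, period = 24, n_cycles = 4, dt = 0.05,
                      amp = 1, offset = 2) {
  t <- seq(0, n_cycles * period, by = dt)
  make_traj(t, list(
    X = offset + amp * cos(2 * pi * (t - peak_at) / period)
  ))
}

test_that("peak time and period are exact on synthetic sinusoids", {
  tr <- sine_traj(peak_at = 6)
  expect_equal(peak_time(tr, "X"), 6, tolerance = 0.01)
  expect_equal(trough_time(tr, "X"), 18, tolerance = 0.01)
  expect_equal(period_estimate(tr, "X"), 24, tolerance = 1e-6)
  tr2 <- sine_traj(peak_at = 13.7, period = 22.5, n_cycles = 5)
  expect_equal(period_estimate(tr2, "X"), 22.5, tolerance = 1e-6)
  # quadratic refinement beats the grid: peak placed off-grid
  tr3 <- sine_traj(peak_at = 6.013)
  expect_equal(peak_time(tr3, "X"), 6.013, tolerance = 1e-3)
  # ZT relabelling offset only moves the label
  expect_equal(peak_time(tr, "X", zt_offset = 10), 16, tolerance = 0.01)
})

test_that("flat signals yield the arrhythmicity sentinel", {
  t <- seq(0, 96, 0.05)
  tr <- make_traj(t, list(X = rep(2, length(t))))
  expect_true(is.na(peak_time(tr, "X")))
  expect_true(is.na(period_estimate(tr, "X")))
  expect_equal(trough_peak_ratio(tr, "X"), 1)
})

test_that("trough/peak ratio is scale-invariant and 1 for constants", {
  tr <- sine_traj()
  r1 <- trough_peak_ratio(tr, "X")
  tr_scaled <- make_traj(tr$time, list(X = 7.3 * tr$state[, "X"]))
  expect_equal(trough_peak_ratio(tr_scaled, "X"), r1, tolerance = 1e-12)
  expect_equal(r1, 1 / 3, tolerance = 1e-4) # (2-1)/(2+1)
})

test_that("phase shift recovers constructed delays", {
  t <- seq(0, 96, 0.05)
  base <- function(delta) {
    make_traj(t, list(P_N = 2 + cos(2 * pi * (t - 6 - delta) / 24)))
  }
  ctl <- base(0)
  expect_equal(phase_shift(ctl, ctl)$shift_hr, rep(0, 4))
  for (delta in c(2, -3.25, 7, 11.5)) {
    sh <- phase_shift(base(delta), ctl)$shift_hr
    expect_equal(sh, rep(delta, 4), tolerance = 0.01)
  }
  # wraparound convention: shifts live in (-12, 12], right shift positive
  sh13 <- phase_shift(base(13), ctl)$shift_hr
  expect_equal(sh13, rep(-11, 4), tolerance = 0.01)
})

test_that("re-entrainment time scans the windowed shift series", {
  t <- seq(0, 7 * 24, 0.05)
  ctl <- make_traj(t, list(P_N = 2 + cos(2 * pi * (t - 6) / 24)))
  expect_equal(reentrainment_time(ctl, ctl), 0)
  # delay decaying day by day: 2, 1.2, 0.7, 0.4, 0.2, 0.1, 0 hours
  lag_by_day <- c(2, 1.2, 0.7, 0.4, 0.2, 0.1, 0)
  lag <- lag_by_day[pmin(floor(t / 24) + 1, 7)]
  trt <- make_traj(t, list(P_N = 2 + cos(2 * pi * (t - 6 - lag) / 24)))
  expect_equal(reentrainment_time(trt, ctl, tol_hr = 0.5), 3)
  # never settles -> sentinel
  drift <- make_traj(t, list(P_N = 2 + cos(2 * pi * (t - 6 - 3) / 24)))
  expect_true(is.na(reentrainment_time(drift, ctl, tol_hr = 0.5)))
})

test_that("rmse matches hand computations and is symmetric", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  x <- c(0.2, 1.7, -0.4)
  y <- c(1.1, 0.3, 0.9)
  expect_equal(rmse(x, y), rmse(y, x))
  expect_equal(rmse(x, y), sqrt(mean((x - y)^2)))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("expression profiles are unit-peak, periodic and consistent", {
  ent <- entrained_ld()
  prof <- expression_profiles(ent)
  expect_equal(max(prof$ETH), 1)
  expect_equal(max(prof$EMAO), 1)
  expect_true(all(prof$ETH > 0 & prof$ETH <= 1))
  expect_true(all(prof$EMAO > 0 & prof$EMAO <= 1))
  # periodic seam
  expect_equal(prof$ETH[1], prof$ETH[nrow(prof)], tolerance = 1e-4)
  expect_equal(prof$EMAO[1], prof$EMAO[nrow(prof)], tolerance = 1e-4)
  # profile trough equals the trough/peak ratio of the raw variable
  expect_equal(min(prof$ETH), trough_peak_ratio(ent, "TH"),
    tolerance = 1e-6
  )
  expect_equal(min(prof$EMAO), trough_peak_ratio(ent, "MAO"),
    tolerance = 1e-6
  )
})

test_that("rhythm summary collates the per-variable metrics", {
  ent <- entrained_ld()
  rs <- rhythm_summary(ent, c("P1", "PC_N", "MAO"))
  expect_equal(rs$variable, c("P1", "PC_N", "MAO"))
  expect_equal(rs$peak_ZT[1], peak_time(ent, "P1"))
  expect_equal(rs$trough_peak_ratio[3], trough_peak_ratio(ent, "MAO"))
  expect_true(all(rs$trough_peak_ratio >= 0 & rs$trough_peak_ratio <= 1))
  expect_true(all(rs$peak_ZT >= 0 & rs$peak_ZT < 24))
  expect_true(all(rs$amplitude_nM > 0))
})

test_that("ventral-striatum relabelling puts the REV-ERB peak at ZT14", {
  ent <- entrained_ld()
  off <- ventral_striatum_offset(ent)
  expect_equal(peak_time(ent, "REV", zt_offset = off), 14, tolerance = 1e-9)
  # relabelling does not change intervals between peaks
  lag <- (peak_time(ent, "P_N", off) - peak_time(ent, "P1", off)) %% 24
  lag0 <- (peak_time(ent, "P_N") - peak_time(ent, "P1")) %% 24
  expect_equal(lag, lag0, tolerance = 1e-9)
})
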