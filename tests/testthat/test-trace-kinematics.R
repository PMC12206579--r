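test_that("lv_trace validates its invariants", {
  t <- seq(0, 1, by = 0.1)
  expect_s3_class(lv_trace(t, sin(t), "pressure_mmHg"), "lv_trace")
  expect_error(lv_trace(t[1:5], sin(t[1:5]), "pressure_mmHg"), "at least 8")
  expect_error(lv_trace(c(t[-1], 2.5), sin(t), "pressure_mmHg"), "uniform")
  expect_error(lv_trace(rev(t), sin(t), "pressure_mmHg"), "increasing")
  tv <- sin(t); tv[3] <- NA
  expect_error(lv_trace(t, tv, "pressure_mmHg"), "missing")
})

test_that("trace CSV round-trip preserves values and infers kind", {
  tr <- lv_trace(seq(0, 1, by = 0.01), rnorm(101), "strain_pct")
  f <- file.path(tempdir(), "p9_strain.csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_identical(back$kind, "strain_pct")
  expect_equal(back$v, tr$v, tolerance = 1e-12)
  expect_error(read_trace_csv(file.path(tempdir(), "p9_strain.csv"),
                              kind = "bogus"))
  file.rename(f, file.path(tempdir(), "mystery.csv"))
  expect_error(read_trace_csv(file.path(tempdir(), "mystery.csv")),
               "cannot infer")
})

test_that("gls_to_volume maps strain anchors linearly", {
  t <- seq(0, 1, by = 0.05)
  gls <- c(0, -5, -10, -20, rep(-20, 3), -15, -10, -5, rep(0, 11))
  vol <- gls_to_volume(lv_trace(t, gls, "strain_pct"), edv = 120, esv = 50)
  expect_equal(vol$v[1], 120)            # zero strain -> EDV
  expect_equal(vol$v[4], 50)             # peak shortening -> ESV
  expect_equal(vol$v[3], 85)             # half shortening -> midway
  # affine invariance: rescaling the strain leaves the volume unchanged
  vol2 <- gls_to_volume(lv_trace(t, 2.5 * gls, "strain_pct"), 120, 50)
  expect_equal(vol2$v, vol$v, tolerance = 1e-12)
  expect_error(gls_to_volume(lv_trace(t, abs(gls), "strain_pct"), 120, 50),
               "invalid strain")
  expect_error(gls_to_volume(lv_trace(t, gls, "strain_pct"), 50, 120),
               "invalid volumes")
})

test_that("flow_and_acceleration differentiates exactly on polynomials", {
  t <- seq(0, 1, by = 0.01)
  opts <- lv_options(smooth_window = 1)   # exactness checks, no smoothing
  fa <- flow_and_acceleration(lv_trace(t, rep(100, length(t)), "volume_mL"),
                              opts)
  expect_equal(max(abs(fa$flow$v)), 0)
  expect_equal(max(abs(fa$accel$v)), 0)
  fa <- flow_and_acceleration(lv_trace(t, 50 + 100 * t, "volume_mL"), opts)
  inner <- 2:(length(t) - 1)
  expect_equal(fa$flow$v[inner], rep(100, length(inner)), tolerance = 1e-9)
  fa <- flow_and_acceleration(lv_trace(t, 50 * t^2, "volume_mL"), opts)
  inner2 <- 3:(length(t) - 2)
  expect_equal(fa$accel$v[inner2], rep(100, length(inner2)),
               tolerance = 1e-6)
})

test_that("flow integrates to the filling volume over diastole", {
  pt <- default_patient()
  vol <- gls_to_volume(pt$traces$strain, pt$scalars$edv, pt$scalars$esv)
  fa <- flow_and_acceleration(vol)
  sel <- fa$flow$t >= pt$events_true$t_mvo
  q <- fa$flow$v[sel]; tt <- fa$flow$t[sel]
  filled <- sum(diff(tt) * (q[-1] + q[-length(q)])) / 2
  fill_true <- pt$scalars$edv - pt$scalars$esv
  expect_lt(abs(filled - fill_true) / fill_true, 0.01)
})

test_that("detect_events recovers simulator event times within one sample", {
  for (seed in c(3, 11, 27)) {
    pt <- default_patient(seed = seed, tau_true = 35 + seed %% 10,
                          pre_a_true = 9 + seed %% 4)
    vol <- gls_to_volume(pt$traces$strain, pt$scalars$edv, pt$scalars$esv)
    fa <- flow_and_acceleration(vol)
    ev <- detect_events(vol, fa$flow, fa$accel)
    dt <- trace_dt(vol)
    for (nm in c("t_mvo", "t_minp", "t_peak_e", "t_a_start", "t_peak_a",
                 "t_mvc"))
      expect_lt(abs(ev[[nm]] - pt$events_true[[nm]]), dt + 1e-9,
                label = sprintf("seed %d, %s", seed, nm))
    expect_false(ev$missing_a)
    # ordering invariant
    tv <- unlist(ev[c("t_mvo", "t_minp", "t_peak_e", "t_a_start",
                      "t_peak_a", "t_mvc")])
    expect_true(all(diff(tv) > 0))
  }
})

test_that("single-wave filling sets the missing-A flag", {
  vol <- single_wave_volume()
  fa <- flow_and_acceleration(vol)
  ev <- detect_events(vol, fa$flow, fa$accel)
  expect_true(ev$missing_a)
  expect_true(is.na(ev$t_a_start) && is.na(ev$t_peak_a))
  expect_equal(ev$t_mvo, 0.40, tolerance = 0.002)
})

test_that("non-physiological traces raise a detection error", {
  t <- seq(0, 1, by = 0.01)
  vol <- lv_trace(t, 120 - 60 * t, "volume_mL")   # emptying only, no filling
  fa <- flow_and_acceleration(vol, lv_options(smooth_window = 1))
  expect_error(detect_events(vol, fa$flow, fa$accel), "detection error")
})

test_that("measure_ivrt recovers the prescribed IVRT", {
  pt <- default_patient(seed = 8)
  vol <- gls_to_volume(pt$traces$strain, pt$scalars$edv, pt$scalars$esv)
  fa <- flow_and_acceleration(vol)
  ivrt <- measure_ivrt(pt$traces$strain, fa$flow)
  expect_lt(abs(1000 * ivrt - pt$true$ivrt_ms), 1.001)  # within one sample
  # AVC after all filling -> no upstroke left, event-order/detection error
  late_strain <- lv_trace(pt$traces$strain$t,
                          -seq_along(pt$traces$strain$t) / 1000,
                          "strain_pct")
  expect_error(measure_ivrt(late_strain, fa$flow), "error")
})
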