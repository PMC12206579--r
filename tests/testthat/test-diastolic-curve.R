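# Build an lv_estimates object directly from known values.
mk_estimates <- function(pre_a, min_plv, edp = NA_real_) {
  structure(list(tau = 40, min_plv = min_plv, pre_a = pre_a,
                 p_mvo = pre_a + 5, max_dp_e = pre_a - min_plv, edp = edp,
                 iterations = 1L, converged = TRUE),
            class = "lv_estimates")
}

test_that("build_reference of one curve is that curve, time-normalized", {
  pt <- default_patient(seed = 3)
  ref <- build_reference(list(annotated_curve(pt$traces$pressure,
                                              pt$events_true)), 100)
  expect_equal(ref$n_sources, 1L)
  # identity reconstruction: same events, anchors equal to the reference's
  cur <- generate_patient_curve(ref, pt$events_true, ref$anchors, 0.005)
  truth <- approx(pt$traces$pressure$t, pt$traces$pressure$v,
                  xout = cur$t)$y
  expect_lt(max(abs(cur$v - truth)), 0.1)
})

test_that("averaging two offset copies gives the midpoint curve", {
  pt <- default_patient(seed = 4)
  tr <- pt$traces$pressure
  tr2 <- lv_trace(tr$t, tr$v + 2, "pressure_mmHg")
  ref1 <- build_reference(list(annotated_curve(tr, pt$events_true)), 80)
  ref <- build_reference(list(annotated_curve(tr, pt$events_true),
                              annotated_curve(tr2, pt$events_true)), 80)
  for (k in 1:5)
    expect_equal(ref$segments[[k]], ref1$segments[[k]] + 1,
                 tolerance = 1e-9)
})

test_that("time-warped copies of one template average back to it", {
  # same anchor pressures, different cycle lengths and volumes -> identical
  # normalized segments; the mean must recover the template
  curves <- lapply(1:8, function(i) {
    p <- simulate_patient(sim_params(seed = i, hr = 52 + 2 * i,
                                     edv = 100 + 5 * i,
                                     esv = (100 + 5 * i) * 0.42))
    annotated_curve(p$traces$pressure, p$events_true)
  })
  ref8 <- build_reference(curves, 100)
  p0 <- simulate_patient(sim_params(seed = 99, hr = 60))
  ref1 <- build_reference(list(annotated_curve(p0$traces$pressure,
                                               p0$events_true)), 100)
  err <- max(sapply(1:5, function(k)
    max(abs(ref8$segments[[k]] - ref1$segments[[k]]))))
  expect_lt(err, 0.1)
})

test_that("curves with missing events are excluded with a warning", {
  pt <- default_patient(seed = 5)
  good <- annotated_curve(pt$traces$pressure, pt$events_true)
  ev_bad <- pt$events_true
  ev_bad$t_a_start <- NA_real_
  bad <- annotated_curve(pt$traces$pressure, ev_bad)
  expect_warning(ref <- build_reference(list(good, bad), 50), "excluded")
  expect_equal(ref$n_sources, 1L)
  expect_error(suppressWarnings(build_reference(list(bad), 50)),
               "no usable curves")
})

test_that("event_pressure_table applies the anchor rules", {
  an <- event_pressure_table(mk_estimates(pre_a = 8, min_plv = 5, edp = 10))
  expect_equal(unname(an[c("mvo", "minp", "a_start", "mvc")]),
               c(13, 5, 8, 10))
  expect_equal(unname(an["peak_a"]), 9)          # midpoint rule
  expect_equal(unname(an["peak_e"]), 8)          # zero gradient at peak E
  # zero gradients everywhere: all anchors at pre-A except MVO and minP
  an0 <- event_pressure_table(mk_estimates(8, 5, edp = 8))
  expect_equal(unname(an0[c("peak_e", "a_start", "peak_a", "mvc")]),
               rep(8, 4))
  # missing EDP falls back with a warning
  expect_warning(
    anf <- event_pressure_table(mk_estimates(8, 5), max_dp_a = 2),
    "falls back")
  expect_equal(unname(anf["mvc"]), 10)
  # ordering violation flagged, not fatal
  expect_warning(
    anw <- event_pressure_table(mk_estimates(8, min_plv = 12, edp = 10)),
    "ordering")
  expect_true(isTRUE(attr(anw, "ordering_warning")))
})

test_that("uniform anchor shifts translate the whole curve", {
  pt <- default_patient(seed = 6)
  ref <- build_reference(list(annotated_curve(pt$traces$pressure,
                                              pt$events_true)), 100)
  base <- generate_patient_curve(ref, pt$events_true, ref$anchors, 0.005)
  up <- generate_patient_curve(ref, pt$events_true, ref$anchors + 2, 0.005)
  expect_equal(up$v, base$v + 2, tolerance = 1e-9)
})

test_that("generated curves pass through the anchors and are continuous", {
  pt <- default_patient(seed = 7)
  ref <- build_reference(list(annotated_curve(pt$traces$pressure,
                                              pt$events_true)), 100)
  target <- ref$anchors + c(1.5, -0.5, 0.3, 1.0, 1.2, 2.0)
  cur <- generate_patient_curve(ref, pt$events_true, target, 0.002)
  et <- c(pt$events_true$t_mvo, pt$events_true$t_minp,
          pt$events_true$t_peak_e, pt$events_true$t_a_start,
          pt$events_true$t_peak_a, pt$events_true$t_mvc)
  at_events <- approx(cur$t, cur$v, xout = et)$y
  expect_equal(unname(at_events), unname(target), tolerance = 0.05)
  # continuity: no jumps beyond a generous local-slope bound
  expect_lt(max(abs(diff(cur$v))),
            5 * max(abs(diff(cur$v[1:50]))) + 0.5)
})

test_that("full reconstruction stays within 1 mmHg RMS of generator truth", {
  curves <- lapply(1:4, function(i) {
    p <- simulate_patient(sim_params(seed = i, pre_a_true = 8 + 2 * i,
                                     tau_true = 35 + 5 * i))
    annotated_curve(p$traces$pressure, p$events_true)
  })
  ref <- build_reference(curves, 100)
  pt <- simulate_patient(sim_params(seed = 55, pre_a_true = 14,
                                    tau_true = 55, lars = 20))
  est <- run_estimate(as_patient_record(pt))
  opts <- lv_options()
  v_pe <- approx(pt$traces$velocity$t, pt$traces$velocity$v,
                 xout = est$events$t_peak_e)$y
  anch <- event_pressure_table(
    est, dp_at_peak_e = (opts$rho_kg_m3 / 2) * v_pe^2 / opts$pa_per_mmHg,
    max_dp_a = est$diagnostics$max_dp_a)
  cur <- generate_patient_curve(ref, est$events, anch)
  truth <- approx(pt$traces$pressure$t, pt$traces$pressure$v,
                  xout = cur$t, rule = 2)$y
  expect_lt(sqrt(mean((cur$v - truth)^2)), 1)
})

test_that("mean_diastolic_pressure integrates exactly on simple shapes", {
  tt <- seq(0, 1, by = 0.01)
  expect_equal(mean_diastolic_pressure(
    lv_trace(tt, rep(8, length(tt)), "pressure_mmHg"), 0, 1), 8)
  ramp <- lv_trace(tt, 4 + 8 * tt, "pressure_mmHg")
  expect_equal(mean_diastolic_pressure(ramp, 0, 1), 8, tolerance = 1e-12)
  step <- lv_trace(tt, ifelse(tt < 0.5, 4, 12), "pressure_mmHg")
  expect_equal(mean_diastolic_pressure(step, 0, 1), 8, tolerance = 0.05)
  # resampling invariance
  t5 <- seq(0, 1, by = 0.005)
  ramp5 <- lv_trace(t5, 4 + 8 * t5, "pressure_mmHg")
  m1 <- mean_diastolic_pressure(ramp, 0.11, 0.93)
  m2 <- mean_diastolic_pressure(ramp5, 0.11, 0.93)
  expect_lt(abs(m1 - m2) / m1, 0.005)
  expect_error(mean_diastolic_pressure(ramp, -0.5, 0.9), "outside")
  expect_error(mean_diastolic_pressure(ramp, 0.9, 0.2), "t_mvo")
})
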