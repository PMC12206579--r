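test_that("sim_params enforces physiological ranges", {
  expect_error(sim_params(psys = 70), "psys")
  expect_error(sim_params(tau_true = 10), "tau_true")
  expect_error(sim_params(pre_a_true = 2), "pre_a_true")
  expect_error(sim_params(edv = 50, esv = 80), "edv > esv")
  expect_error(sim_params(noise_sd = list(bogus = 1)), "noise_sd")
})

test_that("simulation is deterministic for a fixed seed", {
  a <- simulate_patient(sim_params(seed = 9, noise_sd = list(strain = 0.1)))
  b <- simulate_patient(sim_params(seed = 9, noise_sd = list(strain = 0.1)))
  expect_identical(a$traces$strain$v, b$traces$strain$v)
  expect_identical(a$traces$velocity$v, b$traces$velocity$v)
})

test_that("the embedded IVRT inverts the tau estimator", {
  pt <- simulate_patient(sim_params(tau_true = 40, psys = 120,
                                    pre_a_true = 8))
  expect_equal(pt$true$ivrt_ms, (40 / 0.85) * (log(78) - log(13)),
               tolerance = 1e-9)
  # and the generated decay obeys the Weiss model between t0 and MVO
  tr <- pt$traces$pressure
  expect_equal(tr$v[1], 0.65 * 120, tolerance = 0.2)
  p_at_mvo <- approx(tr$t, tr$v, xout = pt$events_true$t_mvo)$y
  expect_equal(p_at_mvo, 13, tolerance = 0.05)
})

test_that("inconsistent parameter combinations are rejected", {
  # P_MVO at/above the decay starting pressure leaves no valid IVRT
  # (within the default ranges this needs a lowered P0 fraction)
  expect_error(simulate_patient(sim_params(psys = 80, pre_a_true = 30,
                                           tau_true = 40),
                                opts = lv_options(p0_fraction = 0.4)),
               "rejection")
  # pre-A below the regression minimum leaves no positive E gradient
  expect_error(simulate_patient(sim_params(pre_a_true = 5, tau_true = 80,
                                           bmi = 35)),
               "rejection")
})

test_that("zero-noise estimates recover the truth for one patient", {
  pt <- simulate_patient(sim_params(seed = 12))
  est <- run_estimate(as_patient_record(pt))
  expect_lt(abs(est$tau - pt$true$tau), 0.5)
  expect_lt(abs(est$pre_a - pt$true$pre_a), 0.05)
  expect_lt(abs(est$edp - pt$true$edp), 0.05)
})

test_that("inverse consistency holds over the (tau, pre-A) plane", {
  # every feasible grid point must recover within discretization bounds
  # (one-sample timing error: ~0.5 ms in tau, ~0.1 mmHg in pressure);
  # infeasible combinations must be clean rejections
  taus <- seq(25, 80, length.out = 10)
  pas <- seq(5, 25, length.out = 10)
  n_ok <- 0L
  for (tv in taus) for (pv in pas) {
    pt <- tryCatch(
      simulate_patient(sim_params(tau_true = tv, pre_a_true = pv, seed = 1)),
      error = function(e) {
        expect_match(conditionMessage(e), "rejection")
        NULL
      })
    if (is.null(pt)) next
    n_ok <- n_ok + 1L
    est <- run_estimate(as_patient_record(pt))
    expect_lt(abs(est$tau - tv), 0.5,
              label = sprintf("tau at (%g, %g)", tv, pv))
    expect_lt(abs(est$pre_a - pv), 0.1,
              label = sprintf("pre_a at (%g, %g)", tv, pv))
  }
  expect_gt(n_ok, 50L)  # most of the plane is physiological
})

test_that("simulate_cohort is reproducible and draws within ranges", {
  co <- simulate_cohort(5, seed = 11)
  co2 <- simulate_cohort(5, seed = 11)
  expect_identical(attr(co, "manifest"), attr(co2, "manifest"))
  man <- attr(co, "manifest")
  expect_true(all(man$tau >= 30 & man$tau <= 65))
  expect_true(all(man$pre_a >= 4 & man$pre_a <= 30))
  expect_equal(man$id, sprintf("p%03d", 1:5))
  one <- simulate_cohort(1, seed = 2)
  expect_length(one, 1L)
  expect_error(simulate_cohort(0), "n must be")
  expect_error(simulate_cohort(2, ranges = list(tau = c(5, 1))),
               "invalid bounds")
})

test_that("recovery_report aligns ids and rejects permutations", {
  co <- simulate_cohort(4, seed = 13)
  ests <- lapply(co, function(p) run_estimate(as_patient_record(p)))
  rep <- recovery_report(co, ests)
  expect_equal(nrow(rep$table), 4L)
  expect_lt(abs(rep$agreement$pre_a$bias), 0.1)
  expect_error(recovery_report(co, rev(ests)), "mismatch")
  expect_error(recovery_report(list(), list()), "empty")
})

test_that("recovery error grows monotonically with strain noise", {
  rmse_at <- function(ns) {
    co <- simulate_cohort(8, noise_sd = list(strain = ns), seed = 5)
    errs <- vapply(seq_along(co), function(i) {
      est <- run_estimate(as_patient_record(co[[i]]))
      est$pre_a - co[[i]]$true$pre_a
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  r <- vapply(c(0, 0.005, 0.02), rmse_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("scalar noise hits the regression but not tau", {
  # LARS enters only the minimum-P_LV regression: noise there must degrade
  # pre-A recovery while leaving tau essentially untouched
  clean <- simulate_cohort(8, seed = 17)
  noisy <- simulate_cohort(8, noise_sd = list(lars = 6), seed = 17)
  err <- function(co, what) vapply(seq_along(co), function(i) {
    est <- run_estimate(as_patient_record(co[[i]]))
    est[[what]] - co[[i]]$true[[what]]
  }, numeric(1))
  expect_gt(sqrt(mean(err(noisy, "pre_a")^2)),
            5 * sqrt(mean(err(clean, "pre_a")^2)))
  # tau is touched only through the p_mvo feedback in the coupled system
  # (~1.8 ms per mmHg of pre-A), so its degradation stays small
  expect_lt(sqrt(mean(err(noisy, "tau")^2)), 3)
})
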