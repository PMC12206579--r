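# Raised-cosine smoothstep from a to b over fraction f in [0, 1]; internal.
smoothstep <- function(a, b, f) a + (b - a) * (1 - cos(pi * f)) / 2

#' Parameters of a synthetic patient
#'
#' The simulator is parameterized by the ground-truth physiology: scalar
#' predictors, the true relaxation constant and true pre-A pressure. All
#' observables are then derived so that, at zero noise, the estimation
#' pipeline applied to the simulated traces recovers the truth (the
#' embedded IVRT is the inverse of the tau estimator; the E-wave peak
#' velocity is chosen so that the transmitral-gradient rule returns exactly
#' pre-A minus the regression's minimum P_LV).
#'
#' @param psys Systolic pressure, mmHg (80-200).
#' @param bmi Body mass index, kg/m^2.
#' @param lars Left atrial reservoir strain, %.
#' @param tau_true True relaxation constant, ms (20-90).
#' @param pre_a_true True pre-A P_LV, mmHg (4-30).
#' @param edv,esv End-diastolic / end-systolic volumes, mL (`edv > esv`).
#' @param hr Heart rate, bpm.
#' @param a_peak_vel Peak A-wave transmitral velocity, m/s.
#' @param e_peak_vel Optional override of the peak E velocity, m/s; `NULL`
#'   (default) derives it from self-consistency.
#' @param dt_s Trace sampling step, s (default 0.001).
#' @param gls_min Peak negative GLS, % (default -20).
#' @param t_avc_frac Aortic valve closure as a fraction of the cycle
#'   (default 0.32).
#' @param e_vol_frac Fraction of the filling volume carried by the E wave
#'   (default 0.6).
#' @param noise_sd Named list of Gaussian noise SDs: `strain` (%-points per
#'   sample), `velocity` (m/s per sample), `psys`, `bmi`, `lars` (scalar
#'   measurement noise). Defaults all 0.
#' @param seed Integer RNG seed for the noise draws.
#' @return A `sim_params` list.
#' @export
sim_params <- function(psys = 120, bmi = 25, lars = 35, tau_true = 40,
                       pre_a_true = 10, edv = 120, esv = 50, hr = 60,
                       a_peak_vel = 0.5, e_peak_vel = NULL, dt_s = 0.001,
                       gls_min = -20, t_avc_frac = 0.32, e_vol_frac = 0.6,
                       noise_sd = list(), seed = 1L) {
  if (psys < 80 || psys > 200) stop("psys outside 80-200 mmHg")
  if (tau_true < 20 || tau_true > 90) stop("tau_true outside 20-90 ms")
  if (pre_a_true < 4 || pre_a_true > 30) stop("pre_a_true outside 4-30 mmHg")
  if (!(edv > esv && esv > 0)) stop("need edv > esv > 0")
  if (hr <= 20 || hr > 150) stop("hr outside plausible range")
  if (gls_min >= 0) stop("gls_min must be negative")
  ns <- list(strain = 0, velocity = 0, psys = 0, bmi = 0, lars = 0)
  bad <- setdiff(names(noise_sd), names(ns))
  if (length(bad)) stop("unknown noise_sd component(s): ",
                        paste(bad, collapse = ", "))
  ns[names(noise_sd)] <- noise_sd
  structure(list(psys = psys, bmi = bmi, lars = lars, tau_true = tau_true,
                 pre_a_true = pre_a_true, edv = edv, esv = esv, hr = hr,
                 a_peak_vel = a_peak_vel, e_peak_vel = e_peak_vel,
                 dt_s = dt_s, gls_min = gls_min, t_avc_frac = t_avc_frac,
                 e_vol_frac = e_vol_frac, noise_sd = ns,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate one synthetic patient
#'
#' Forward model of one cardiac cycle on a uniform grid (`dt_s`), starting
#' at end-diastole:
#' ejection (half-cosine volume fall EDV to ESV until `t_avc_frac` of the
#' cycle), an isovolumic plateau of duration IVRT, then raised-cosine E and
#' A filling waves separated by diastasis and ending at end-diastole (MVC).
#' The GLS trace mirrors the volume curve (zero at end-diastole, `gls_min`
#' at end-systole); transmitral velocity is the filling flow divided by the
#' effective orifice area. The true diastolic pressure curve runs Weiss
#' decay from 0.65 P_sys to P_MVO over 0.85 IVRT, then raised-cosine
#' segments through the event anchors down to minimum P_LV and up to EDP.
#'
#' Internal consistency at zero noise: IVRT inverts the tau estimator,
#' minimum P_LV follows the regression at (psys, bmi, lars, tau_true), and
#' the E-wave peak velocity satisfies pre_a = min P_LV + max dP_E under the
#' transmitral-gradient rule, so the estimation pipeline recovers the truth
#' to solver/discretization tolerance.
#'
#' @param params A [sim_params()] object.
#' @param opts Options from [lv_options()] (model constants shared with the
#'   estimator).
#' @return An object of class `lv_synth_patient`: `id`, `scalars` (observed,
#'   possibly noisy), `traces` (`strain`, `velocity`, and diastolic
#'   `pressure`), `events_true`, `true` (tau, min_plv, pre_a, p_mvo, edp,
#'   max_dp_e, max_dp_a, ivrt_ms), `params`.
#' @export
#' @examples
#' pt <- simulate_patient(sim_params(seed = 7))
#' pt$true$ivrt_ms
simulate_patient <- function(params = sim_params(), opts = lv_options()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  p0 <- opts$p0_fraction * p$psys
  p_mvo <- p$pre_a_true + opts$p_mvo_offset_mmHg
  if (p_mvo >= p0)
    stop(sprintf(
      "rejection: pre_a + %g = %.3g mmHg >= %.3g * psys = %.3g mmHg",
      opts$p_mvo_offset_mmHg, p_mvo, opts$p0_fraction, p0))
  ivrt_ms <- p$tau_true * (log(p0) - log(p_mvo)) / opts$tau_ivrt_factor
  min_plv <- estimate_min_plv(p$psys, p$bmi, p$lars, p$tau_true)
  dpe <- p$pre_a_true - min_plv
  if (dpe <= 0)
    stop(sprintf(
      "rejection: pre_a_true (%.3g) <= regression min P_LV (%.3g); no positive E gradient",
      p$pre_a_true, min_plv))
  rho <- opts$rho_kg_m3
  # onset-rule gradient maximum is rho * v^2 at the wave peak
  v_e <- if (is.null(p$e_peak_vel)) sqrt(dpe * opts$pa_per_mmHg / rho)
         else p$e_peak_vel
  fill <- p$edv - p$esv
  vol_e <- p$e_vol_frac * fill
  vol_a <- fill - vol_e

  period <- 60 / p$hr
  n <- round(period / p$dt_s) + 1L
  t <- seq(0, period, length.out = n)
  dt <- period / (n - 1L)           # actual grid step
  t_avc <- round(p$t_avc_frac * (n - 1L)) * dt  # grid-aligned truth
  t_mvo <- t_avc + ivrt_ms / 1000

  # effective orifice: velocities (hence gradients) are fixed by
  # self-consistency, so the area only sets how fast the stroke volume
  # passes; enlarge it above the default when the filling waves would not
  # fit into diastole, within a physiological cap
  avail <- period - t_mvo - 3 * dt
  if (avail <= 0)
    stop("rejection: infeasible timing (isovolumic relaxation fills diastole)")
  area_req <- (2 * vol_e / v_e + 2 * vol_a / p$a_peak_vel) / (100 * avail)
  area <- max(opts$orifice_cm2, 1.02 * area_req)
  if (area > 6.5)
    stop(sprintf(
      "rejection: infeasible timing (needs orifice %.2f cm^2 > 6.5 cm^2 cap)",
      area))
  q_e <- v_e * area * 100           # mL/s through area cm^2 at v m/s
  q_a <- p$a_peak_vel * area * 100
  d_e <- 2 * vol_e / q_e            # raised-cosine wave: volume = peak*dur/2
  d_a <- 2 * vol_a / q_a
  t_as <- period - d_a

  # piecewise volume trace
  v <- numeric(n)
  seg1 <- t <= t_avc
  v[seg1] <- p$esv + (p$edv - p$esv) * (1 + cos(pi * t[seg1] / t_avc)) / 2
  v[t > t_avc] <- p$esv
  ine <- t > t_mvo & t <= t_mvo + d_e
  se <- (t[ine] - t_mvo) / d_e
  v[ine] <- p$esv + vol_e * (se - sin(2 * pi * se) / (2 * pi))
  v[t > t_mvo + d_e & t <= t_as] <- p$esv + vol_e
  ina <- t > t_as
  sa <- (t[ina] - t_as) / d_a
  v[ina] <- p$esv + vol_e + vol_a * (sa - sin(2 * pi * sa) / (2 * pi))

  strain_v <- p$gls_min * (p$edv - v) / (p$edv - p$esv)

  # analytic transmitral flow -> velocity (zero outside filling)
  qv <- numeric(n)
  qv[ine] <- q_e * (1 - cos(2 * pi * se)) / 2
  qv[ina] <- q_a * (1 - cos(2 * pi * sa)) / 2
  vel_v <- qv / (area * 100)

  # true diastolic event times
  t_minp <- t_mvo + d_e / 4
  t_peak_e <- t_mvo + d_e / 2
  t_peak_a <- t_as + d_a / 2
  events_true <- lv_events(t_avc = t_avc, t_mvo = t_mvo, t_minp = t_minp,
                           t_peak_e = t_peak_e, t_a_start = t_as,
                           t_peak_a = t_peak_a, t_mvc = period)

  dpa <- rho * p$a_peak_vel^2 / opts$pa_per_mmHg
  edp <- p$pre_a_true + dpa + opts$passive_rise_mmHg
  p_peak_e <- p$pre_a_true - (rho / 2) * v_e^2 / opts$pa_per_mmHg
  p_peak_a <- (p$pre_a_true + edp) / 2

  # diastolic pressure curve: Weiss decay from its onset t0 to MVO, then
  # raised-cosine segments through the event anchors to MVC
  t0 <- t_mvo - opts$tau_ivrt_factor * ivrt_ms / 1000
  dia <- t >= t0
  td <- t[dia]
  pd <- numeric(length(td))
  iso <- td <= t_mvo
  pd[iso] <- p0 * exp(-(td[iso] - t0) * 1000 / p$tau_true)
  anchors_t <- c(t_mvo, t_minp, t_peak_e, t_as, t_peak_a, period)
  anchors_p <- c(p_mvo, min_plv, p_peak_e, p$pre_a_true, p_peak_a, edp)
  for (k in seq_len(length(anchors_t) - 1L)) {
    sel <- td > anchors_t[k] & td <= anchors_t[k + 1L]
    f <- (td[sel] - anchors_t[k]) / (anchors_t[k + 1L] - anchors_t[k])
    pd[sel] <- smoothstep(anchors_p[k], anchors_p[k + 1L], f)
  }

  set.seed(p$seed)
  ns <- p$noise_sd
  if (ns$strain > 0) strain_v <- strain_v + stats::rnorm(n, 0, ns$strain)
  if (ns$velocity > 0) vel_v <- pmax(vel_v + stats::rnorm(n, 0, ns$velocity), 0)
  scalars <- list(
    psys = p$psys + if (ns$psys > 0) stats::rnorm(1, 0, ns$psys) else 0,
    bmi  = p$bmi  + if (ns$bmi  > 0) stats::rnorm(1, 0, ns$bmi)  else 0,
    lars = p$lars + if (ns$lars > 0) stats::rnorm(1, 0, ns$lars) else 0,
    edv = p$edv, esv = p$esv, hr = p$hr)

  structure(list(
    id = sprintf("sim-seed%d", p$seed),
    scalars = scalars,
    traces = list(strain = lv_trace(t, strain_v, "strain_pct"),
                  velocity = lv_trace(t, vel_v, "velocity_m_per_s"),
                  pressure = lv_trace(td, pd, "pressure_mmHg")),
    events_true = events_true,
    true = list(tau = p$tau_true, min_plv = min_plv, pre_a = p$pre_a_true,
                p_mvo = p_mvo, edp = edp, max_dp_e = dpe, max_dp_a = dpa,
                ivrt_ms = ivrt_ms),
    params = p), class = "lv_synth_patient")
}

#' @export
print.lv_synth_patient <- function(x, ...) {
  cat(sprintf(
    "<lv_synth_patient %s> tau = %.1f ms, pre-A = %.1f mmHg, EDP = %.1f mmHg, IVRT = %.1f ms\n",
    x$id, x$true$tau, x$true$pre_a, x$true$edp, x$true$ivrt_ms))
  invisible(x)
}

#' Simulate a cohort of synthetic patients
#'
#' Draws patient parameters independently from uniform ranges and runs
#' [simulate_patient()]. The true pre-A pressure is constructed as the
#' regression minimum P_LV plus a drawn E-wave gradient, which keeps every
#' draw self-consistent; draws that still violate a physiological or
#' timing constraint are rejected and redrawn (deterministically, given
#' `seed`).
#'
#' @param n Number of patients (>= 1).
#' @param ranges Named list of `c(lo, hi)` uniform ranges for `psys`,
#'   `bmi`, `lars`, `tau`, `dpe` (E gradient, mmHg), `a_peak_vel`, `edv`,
#'   `esv_frac` (ESV/EDV), `hr`. Partial overrides allowed.
#' @param noise_sd Passed to [sim_params()].
#' @param seed Cohort seed.
#' @param dt_s Trace sampling step, s.
#' @param opts Options from [lv_options()].
#' @return A list of `lv_synth_patient` objects with attribute `manifest`,
#'   a data frame of the drawn true parameters.
#' @export
simulate_cohort <- function(n, ranges = list(), noise_sd = list(),
                            seed = 1L, dt_s = 0.001, opts = lv_options()) {
  if (n < 1L) stop("n must be >= 1")
  rg <- list(psys = c(100, 160), bmi = c(20, 35), lars = c(15, 45),
             tau = c(30, 65), dpe = c(1.5, 5), a_peak_vel = c(0.4, 0.7),
             edv = c(100, 160), esv_frac = c(0.35, 0.5), hr = c(55, 65))
  bad <- setdiff(names(ranges), names(rg))
  if (length(bad)) stop("unknown range(s): ", paste(bad, collapse = ", "))
  rg[names(ranges)] <- ranges
  for (nm in names(rg))
    if (length(rg[[nm]]) != 2L || rg[[nm]][1] > rg[[nm]][2])
      stop("invalid bounds for range: ", nm)
  set.seed(seed)
  cohort <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pt <- NULL
    for (attempt in 1:200) {
      draw <- lapply(rg, function(b) stats::runif(1, b[1], b[2]))
      minp <- estimate_min_plv(draw$psys, draw$bmi, draw$lars, draw$tau)
      pre_a <- minp + draw$dpe
      pseed <- sample.int(.Machine$integer.max - 1L, 1L)
      pt <- tryCatch({
        if (pre_a < 4 || pre_a > 30) stop("rejection: pre-A outside 4-30")
        sp <- sim_params(psys = draw$psys, bmi = draw$bmi, lars = draw$lars,
                         tau_true = draw$tau, pre_a_true = pre_a,
                         edv = draw$edv, esv = draw$esv_frac * draw$edv,
                         hr = draw$hr, a_peak_vel = draw$a_peak_vel,
                         dt_s = dt_s, noise_sd = noise_sd, seed = pseed)
        simulate_patient(sp, opts)
      }, error = function(e) {
        if (grepl("rejection", conditionMessage(e))) NULL else stop(e)
      })
      if (!is.null(pt)) break
    }
    if (is.null(pt))
      stop("could not draw a feasible patient in 200 attempts; widen ranges")
    pt$id <- sprintf("p%03d", i)
    cohort[[i]] <- pt
    rows[[i]] <- data.frame(id = pt$id, tau = pt$true$tau,
                            min_plv = pt$true$min_plv, pre_a = pt$true$pre_a,
                            edp = pt$true$edp, psys = pt$params$psys,
                            lars = pt$params$lars, hr = pt$params$hr)
  }
  attr(cohort, "manifest") <- do.call(rbind, rows)
  cohort
}

#' Parameter-recovery report on a synthetic cohort
#'
#' Bland-Altman and regression agreement of estimated vs true tau, minimum
#' P_LV, pre-A P_LV and EDP. Estimates must carry the ids of the cohort
#' patients in the same order (guards against permuted inputs).
#'
#' @param cohort Output of [simulate_cohort()].
#' @param estimates List of `lv_estimates` (e.g. from [run_estimate()]),
#'   each with an `id` field matching its patient.
#' @return A list with `table` (data frame of true and estimated values)
#'   and `agreement`, a named list of [agreement_stats()] per parameter.
#' @export
recovery_report <- function(cohort, estimates) {
  if (!length(cohort)) stop("empty cohort")
  if (length(cohort) != length(estimates))
    stop("cohort and estimates must have equal length")
  ids_c <- vapply(cohort, function(p) p$id, character(1))
  ids_e <- vapply(estimates, function(e)
    if (is.null(e$id)) NA_character_ else e$id, character(1))
  if (anyNA(ids_e) || !identical(ids_c, ids_e))
    stop("mismatch error: estimate ids do not align with cohort ids")
  tab <- data.frame(
    id = ids_c,
    tau_true = vapply(cohort, function(p) p$true$tau, numeric(1)),
    tau_est = vapply(estimates, function(e) e$tau, numeric(1)),
    min_plv_true = vapply(cohort, function(p) p$true$min_plv, numeric(1)),
    min_plv_est = vapply(estimates, function(e) e$min_plv, numeric(1)),
    pre_a_true = vapply(cohort, function(p) p$true$pre_a, numeric(1)),
    pre_a_est = vapply(estimates, function(e) e$pre_a, numeric(1)),
    edp_true = vapply(cohort, function(p) p$true$edp, numeric(1)),
    edp_est = vapply(estimates, function(e) e$edp, numeric(1)))
  agr <- list(
    tau = agreement_stats(tab$tau_est, tab$tau_true),
    min_plv = agreement_stats(tab$min_plv_est, tab$min_plv_true),
    pre_a = agreement_stats(tab$pre_a_est, tab$pre_a_true),
    edp = agreement_stats(tab$edp_est, tab$edp_true))
  list(table = tab, agreement = agr)
}
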