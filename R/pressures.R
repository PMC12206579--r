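#' Linear model for minimum LV pressure
#'
#' Cohort-derived multivariable regression predicting minimum P_LV (mmHg)
#' from systolic pressure, BMI, left atrial reservoir strain (LARS) and the
#' relaxation time constant tau:
#' \deqn{minP_{LV} \approx -6.885 + 0.025\,P_{sys} + 0.243\,BMI
#'   - 0.097\,LARS + 0.158\,\tau.}
#'
#' @param intercept,coef_psys,coef_bmi,coef_lars,coef_tau Model
#'   coefficients; defaults are the published values.
#' @return A `min_plv_model` list.
#' @export
min_plv_model <- function(intercept = -6.885, coef_psys = 0.025,
                          coef_bmi = 0.243, coef_lars = -0.097,
                          coef_tau = 0.158) {
  m <- list(intercept = intercept, coef_psys = coef_psys, coef_bmi = coef_bmi,
            coef_lars = coef_lars, coef_tau = coef_tau)
  if (!all(vapply(m, is.finite, logical(1)))) stop("coefficients must be finite")
  structure(m, class = "min_plv_model")
}

#' Estimate minimum LV pressure
#'
#' @param psys Systolic pressure, mmHg.
#' @param bmi Body mass index, kg/m^2.
#' @param lars Left atrial reservoir strain, % (positive).
#' @param tau Relaxation time constant, ms.
#' @param model A [min_plv_model()].
#' @return Minimum P_LV in mmHg.
#' @export
#' @examples
#' estimate_min_plv(120, 25, 35, 50)  # 6.695 mmHg
estimate_min_plv <- function(psys, bmi, lars, tau, model = min_plv_model()) {
  stopifnot(inherits(model, "min_plv_model"))
  model$intercept + model$coef_psys * psys + model$coef_bmi * bmi +
    model$coef_lars * lars + model$coef_tau * tau
}

#' Pre-atrial-contraction LV pressure (LV filling pressure)
#'
#' Pre-A P_LV, the surrogate for mean left atrial pressure, is the sum of
#' minimum P_LV and the maximum early-diastolic transmitral pressure
#' difference.
#'
#' @param min_plv Minimum LV pressure, mmHg.
#' @param max_dp_e Maximum E-wave transmitral pressure difference, mmHg
#'   (>= 0).
#' @return Pre-A P_LV in mmHg.
#' @export
estimate_pre_a <- function(min_plv, max_dp_e) {
  if (max_dp_e < 0) stop("invalid gradient: max_dp_e must be >= 0")
  min_plv + max_dp_e
}

#' Patient scalar inputs
#'
#' Bundle of the scalar measurements consumed by the coupled solver.
#'
#' @param psys Systolic pressure, mmHg (> 0).
#' @param bmi Body mass index, kg/m^2 (> 0).
#' @param lars Left atrial reservoir strain, % (>= 0).
#' @param ivrt_ms Isovolumic relaxation time, ms (> 0).
#' @param max_dp_e Maximum E-wave transmitral pressure difference, mmHg
#'   (>= 0).
#' @param max_dp_a Optional maximum A-wave pressure difference, mmHg.
#' @param passive_rise Optional passive-filling pressure rise, mmHg.
#' @return A `patient_scalars` list.
#' @export
patient_scalars <- function(psys, bmi, lars, ivrt_ms, max_dp_e,
                            max_dp_a = NA_real_, passive_rise = 0) {
  if (psys <= 0 || bmi <= 0 || lars < 0 || ivrt_ms <= 0 || max_dp_e < 0)
    stop("patient scalars outside valid ranges")
  structure(list(psys = psys, bmi = bmi, lars = lars, ivrt_ms = ivrt_ms,
                 max_dp_e = max_dp_e, max_dp_a = max_dp_a,
                 passive_rise = passive_rise),
            class = "patient_scalars")
}

#' Coupled estimation of tau, minimum P_LV, pre-A P_LV and P_MVO
#'
#' P_MVO depends on pre-A P_LV (P_MVO = pre-A + 5 mmHg), tau depends on
#' P_MVO, minimum P_LV depends on tau, and pre-A depends on minimum P_LV —
#' a coupled system solved by sequential fixed-point iteration:
#' P_MVO <- pre-A + offset; tau <- [estimate_tau()]; minP <-
#' [estimate_min_plv()]; pre-A <- minP + max_dp_e; repeated until the
#' largest change across the four unknowns falls below `opts$solver_tol_mmHg`
#' (default 0.01) or `opts$solver_max_iter` (default 10) is reached.
#'
#' @param scalars A [patient_scalars()] bundle.
#' @param model A [min_plv_model()].
#' @param opts Options from [lv_options()]; `init_pre_a_mmHg` sets the
#'   starting point.
#' @return An object of class `lv_estimates`: list with `tau` (ms),
#'   `min_plv`, `pre_a`, `p_mvo`, `max_dp_e`, `edp` (NA until
#'   [estimate_edp()]), `iterations`, `converged`, and a `history` data
#'   frame of iterates.
#' @export
#' @examples
#' sc <- patient_scalars(psys = 120, bmi = 25, lars = 35, ivrt_ms = 80,
#'                       max_dp_e = 3)
#' solve_coupled(sc)  # pre_a ~ 7.72 mmHg, tau ~ 37.5 ms
solve_coupled <- function(scalars, model = min_plv_model(),
                          opts = lv_options()) {
  stopifnot(inherits(scalars, "patient_scalars"))
  off <- opts$p_mvo_offset_mmHg
  p0 <- opts$p0_fraction * scalars$psys
  pre_a <- opts$init_pre_a_mmHg
  if (p0 <= pre_a + off)
    stop(sprintf(
      "divergence error: %.3g * psys = %.3g mmHg <= init pre-A + %g mmHg (psys too low)",
      opts$p0_fraction, p0, off))
  prev <- c(NA_real_, NA_real_, NA_real_, NA_real_)
  hist <- vector("list", opts$solver_max_iter)
  converged <- FALSE
  it <- 0L
  tau <- minp <- NA_real_
  while (it < opts$solver_max_iter) {
    it <- it + 1L
    p_mvo <- pre_a + off
    if (p_mvo >= p0)
      stop(sprintf(
        "divergence error: iterate p_mvo = %.3g mmHg reached %.3g * psys = %.3g mmHg (psys = %.4g, ivrt = %.4g ms, max_dp_e = %.3g)",
        p_mvo, opts$p0_fraction, p0, scalars$psys, scalars$ivrt_ms,
        scalars$max_dp_e))
    tau <- estimate_tau(scalars$ivrt_ms, scalars$psys, p_mvo, opts)
    minp <- estimate_min_plv(scalars$psys, scalars$bmi, scalars$lars, tau,
                             model)
    pre_a_new <- estimate_pre_a(minp, scalars$max_dp_e)
    cur <- c(p_mvo, tau, minp, pre_a_new)
    hist[[it]] <- data.frame(iteration = it, p_mvo = p_mvo, tau = tau,
                             min_plv = minp, pre_a = pre_a_new)
    # first pass: only the pre-A update is comparable (so initializing at
    # the fixed point converges in one iteration)
    delta <- if (anyNA(prev)) abs(pre_a_new - pre_a) else max(abs(cur - prev))
    prev <- cur
    pre_a <- pre_a_new
    if (delta < opts$solver_tol_mmHg) { converged <- TRUE; break }
  }
  structure(list(tau = tau, min_plv = minp, pre_a = pre_a,
                 p_mvo = pre_a + off, max_dp_e = scalars$max_dp_e,
                 edp = NA_real_, iterations = it, converged = converged,
                 history = do.call(rbind, hist[seq_len(it)])),
            class = "lv_estimates")
}

#' @export
print.lv_estimates <- function(x, ...) {
  cat(sprintf(paste0(
    "<lv_estimates> tau = %.2f ms, min P_LV = %.2f, pre-A = %.2f, ",
    "P_MVO = %.2f mmHg%s (%d iteration%s, %sconverged)\n"),
    x$tau, x$min_plv, x$pre_a, x$p_mvo,
    if (is.na(x$edp)) "" else sprintf(", EDP = %.2f mmHg", x$edp),
    x$iterations, if (x$iterations == 1L) "" else "s",
    if (x$converged) "" else "NOT "))
  invisible(x)
}

#' End-diastolic LV pressure
#'
#' EDP = pre-A P_LV + maximum A-wave transmitral pressure difference +
#' passive-filling pressure rise. With a fused E/A wave (`max_dp_a = NA`)
#' the result is `NA` rather than an error.
#'
#' @param pre_a Pre-A P_LV, mmHg.
#' @param max_dp_a Maximum A-wave pressure difference, mmHg (>= 0), or `NA`.
#' @param passive_rise Passive-filling pressure rise, mmHg (>= 0, default 0).
#' @return EDP in mmHg, or `NA` when the A wave is unavailable.
#' @export
estimate_edp <- function(pre_a, max_dp_a, passive_rise = 0) {
  if (is.na(max_dp_a)) return(NA_real_)
  if (max_dp_a < 0 || passive_rise < 0)
    stop("max_dp_a and passive_rise must be >= 0")
  pre_a + max_dp_a + passive_rise
}
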