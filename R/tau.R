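#' Weiss exponential pressure decay
#'
#' Isovolumic LV pressure decay P(t) = P0 exp(-t / tau), with P0 the
#' pressure at the onset of the decay (peak negative dP/dt) and tau the
#' relaxation time constant.
#'
#' @param p0 Pressure at decay onset, mmHg (> 0).
#' @param tau Relaxation time constant, ms (> 0).
#' @param t_ms Time(s) since decay onset, ms (>= 0); vectorized.
#' @return Pressure(s) in mmHg.
#' @export
#' @examples
#' weiss_pressure(78, 40, c(0, 40, 80))  # 78, 78/e, 78/e^2
weiss_pressure <- function(p0, tau, t_ms) {
  if (!(is.numeric(tau) && all(tau > 0))) stop("invalid parameter: tau must be > 0")
  if (!(is.numeric(p0) && all(p0 > 0))) stop("invalid parameter: p0 must be > 0")
  if (any(t_ms < 0)) stop("t_ms must be >= 0")
  p0 * exp(-t_ms / tau)
}

#' Non-invasive estimate of the relaxation time constant tau
#'
#' Assumes the decay starts at a fixed fraction of systolic pressure
#' (`opts$p0_fraction`, default 0.65) and lasts a fixed fraction of IVRT
#' (`opts$tau_ivrt_factor`, default 0.85) down to the pressure at mitral
#' valve opening:
#' \deqn{\tau = \frac{0.85\,IVRT}{\ln(0.65\,P_{sys}) - \ln(P_{MVO})}.}
#'
#' @param ivrt_ms Isovolumic relaxation time, ms (> 0).
#' @param psys Systolic (cuff) pressure, mmHg.
#' @param p_mvo LV pressure at mitral valve opening, mmHg; must satisfy
#'   `0 < p_mvo < p0_fraction * psys`.
#' @param opts Options from [lv_options()].
#' @return tau in ms.
#' @export
#' @examples
#' estimate_tau(80, 120, 15)  # 41.245 ms
estimate_tau <- function(ivrt_ms, psys, p_mvo, opts = lv_options()) {
  if (ivrt_ms <= 0) stop("ivrt must be > 0")
  p0 <- opts$p0_fraction * psys
  if (!(p_mvo > 0 && p_mvo < p0))
    stop(sprintf(
      "non-physiological pressures: need 0 < p_mvo < %.3g * psys = %.3g mmHg (got p_mvo = %.3g)",
      opts$p0_fraction, p0, p_mvo))
  opts$tau_ivrt_factor * ivrt_ms / (log(p0) - log(p_mvo))
}

#' Sensitivity of the tau estimate to input errors
#'
#' Recomputes tau after perturbing one input at a time and tabulates the
#' signed change. Perturbations that push the inputs outside the valid
#' domain (p_mvo >= p0_fraction * psys, or non-positive values) are flagged
#' rather than raising an error.
#'
#' @param ivrt_ms,psys,p_mvo Baseline inputs of [estimate_tau()].
#' @param deltas Named list of numeric perturbation vectors; names among
#'   `"ivrt_ms"`, `"psys"`, `"p_mvo"`.
#' @param opts Options from [lv_options()].
#' @return A data frame with columns `input`, `delta`, `tau_base_ms`,
#'   `tau_perturbed_ms`, `delta_tau_ms`, `valid`.
#' @export
#' @examples
#' tau_sensitivity(80, 120, 15, deltas = list(p_mvo = c(-5, 5), psys = 15))
tau_sensitivity <- function(ivrt_ms, psys, p_mvo,
                            deltas = list(ivrt_ms = c(-8, 8),
                                          psys = c(-15, 15),
                                          p_mvo = c(-5, 5)),
                            opts = lv_options()) {
  bad <- setdiff(names(deltas), c("ivrt_ms", "psys", "p_mvo"))
  if (length(bad)) stop("unknown input(s) in deltas: ", paste(bad, collapse = ", "))
  tau0 <- estimate_tau(ivrt_ms, psys, p_mvo, opts)
  rows <- list()
  for (nm in names(deltas)) {
    for (d in deltas[[nm]]) {
      args <- list(ivrt_ms = ivrt_ms, psys = psys, p_mvo = p_mvo)
      args[[nm]] <- args[[nm]] + d
      taup <- tryCatch(
        estimate_tau(args$ivrt_ms, args$psys, args$p_mvo, opts),
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        input = nm, delta = d, tau_base_ms = tau0,
        tau_perturbed_ms = taup, delta_tau_ms = taup - tau0,
        valid = !is.na(taup))
    }
  }
  do.call(rbind, rows)
}
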