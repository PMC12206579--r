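#' Transmitral pressure difference (simplified Navier-Stokes)
#'
#' Pointwise atrio-ventricular pressure difference across the mitral valve
#' from the transmitral velocity, flow rate and flow-rate increment:
#' \deqn{\Delta P = \frac{\rho}{2}\left(v_{MV}^2 +
#'   \frac{Q\,v_{MV}^2}{\Delta Q}\right)}
#' in Pa, converted to mmHg (1 mmHg = 133.322 Pa). Q/deltaQ is a
#' dimensionless ratio (both mL/s). With the inertial term suppressed
#' (q = 0) this reduces to the simplified Bernoulli value (rho/2) v^2.
#'
#' @param v_mv Transmitral velocity, m/s (>= 0); vectorized.
#' @param q Flow rate, mL/s.
#' @param delta_q Flow-rate increment, mL/s (non-zero).
#' @param opts Options from [lv_options()] (`rho_kg_m3`, `pa_per_mmHg`).
#' @return Pressure difference(s) in mmHg.
#' @export
#' @examples
#' transmitral_dp(1, 0, 600)     # convective-only: 3.975 mmHg at rho = 1060
#' transmitral_dp(1, 300, 600)   # 5.963 mmHg
transmitral_dp <- function(v_mv, q = 0, delta_q = 1, opts = lv_options()) {
  if (any(delta_q == 0))
    stop("division error: delta_q = 0; use q = 0 for the convective-only form")
  if (any(v_mv < 0)) stop("v_mv must be >= 0")
  pa <- (opts$rho_kg_m3 / 2) * v_mv^2 * (1 + q / delta_q)
  pa / opts$pa_per_mmHg
}

#' Time window of one filling wave
#'
#' @param t_start,t_end Window bounds in seconds (`t_start < t_end`).
#' @param label `"E"` or `"A"`.
#' @return A `wave_window` list.
#' @export
wave_window <- function(t_start, t_end, label = c("E", "A")) {
  label <- match.arg(label)
  if (!(t_start < t_end)) stop("t_start must be < t_end")
  structure(list(t_start = t_start, t_end = t_end, label = label),
            class = "wave_window")
}

#' Maximum transmitral pressure difference over one filling wave
#'
#' Evaluates [transmitral_dp()] at every sample of the window and returns
#' the maximum and its time. The flow increment deltaQ follows
#' `opts$dq_rule`:
#' \describe{
#'   \item{`"onset"`}{deltaQ(t) = Q(t) - Q(window start), per sample
#'     (default).}
#'   \item{`"fixed"`}{constant per wave, Q_peak - Q_onset.}
#'   \item{`"diff"`}{per-sample backward difference of Q.}
#' }
#' |deltaQ| is floored at `opts$dq_floor_frac` of the window's peak |Q| to
#' avoid blow-up near the onset where both Q and deltaQ vanish.
#'
#' @param v_trace Velocity trace (kind `velocity_m_per_s`).
#' @param q_trace Flow trace (kind `flow_mL_per_s`) on a compatible grid.
#' @param window A [wave_window()].
#' @param opts Options from [lv_options()].
#' @return A list with `dp_mmHg`, `t_s` (time of the maximum) and a
#'   `diagnostics` data frame (`time_s`, `dp_mmHg`) over the window.
#' @export
max_dp_over_wave <- function(v_trace, q_trace, window, opts = lv_options()) {
  stopifnot(inherits(v_trace, "lv_trace"), inherits(q_trace, "lv_trace"),
            inherits(window, "wave_window"))
  vw <- trace_window(v_trace, window$t_start, window$t_end)
  if (length(vw$t) == 0L) stop("empty window: no velocity samples in window")
  q <- stats::approx(q_trace$t, q_trace$v, xout = vw$t, rule = 2)$y
  if (all(vw$v == 0))
    return(list(dp_mmHg = 0, t_s = window$t_start,
                diagnostics = data.frame(time_s = vw$t, dp_mmHg = 0)))
  q_on <- q[1L]
  dq <- switch(opts$dq_rule,
    onset = q - q_on,
    fixed = rep(max(q) - q_on, length(q)),
    diff  = c(q[2L] - q[1L], diff(q)),
    stop("unknown dq_rule: ", opts$dq_rule))
  floorv <- opts$dq_floor_frac * max(abs(q))
  s <- ifelse(dq >= 0, 1, -1)
  dq <- s * pmax(abs(dq), floorv)
  dp <- transmitral_dp(pmax(vw$v, 0), q, dq, opts)
  i <- which.max(dp)
  list(dp_mmHg = dp[i], t_s = vw$t[i],
       diagnostics = data.frame(time_s = vw$t, dp_mmHg = dp))
}
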