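#' Convert a global longitudinal strain trace to an LV volume trace
#'
#' The LV volume curve is assumed to mirror the GLS curve: the strain trace
#' is scaled linearly so that zero strain maps to end-diastolic volume (EDV)
#' and the most negative strain maps to end-systolic volume (ESV):
#' \deqn{V(t) = EDV + \frac{GLS(t)}{GLS_{min}} (ESV - EDV).}
#'
#' @param strain An [lv_trace()] of kind `strain_pct`, negative at
#'   end-systole, zero at end-diastole.
#' @param edv End-diastolic volume, mL.
#' @param esv End-systolic volume, mL (`0 < esv < edv`).
#' @return An `lv_trace` of kind `volume_mL` on the same time grid.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' gls <- -20 * sin(pi * pmin(t, 0.5) / 0.5)^2
#' vol <- gls_to_volume(lv_trace(t, gls, "strain_pct"), edv = 120, esv = 50)
gls_to_volume <- function(strain, edv, esv) {
  stopifnot(inherits(strain, "lv_trace"))
  if (strain$kind != "strain_pct") stop("strain trace must have kind 'strain_pct'")
  if (!(edv > esv && esv > 0)) stop("invalid volumes: need edv > esv > 0")
  gmin <- min(strain$v)
  if (gmin >= 0) stop("invalid strain: most negative GLS must be < 0")
  v <- edv + (strain$v / gmin) * (esv - edv)
  lv_trace(strain$t, v, "volume_mL")
}

#' Transmitral flow rate and flow acceleration from a volume trace
#'
#' Computes Q = dV/dt and dQ/dt = d2V/dt2 by central differences (one-sided
#' at the end points). A centred moving average (`opts$smooth_window`) is
#' applied before each differentiation; second derivatives amplify noise, so
#' disable smoothing only for analytically clean inputs.
#'
#' @param volume An [lv_trace()] of kind `volume_mL`.
#' @param opts Options from [lv_options()].
#' @return A list with elements `flow` (kind `flow_mL_per_s`) and `accel`
#'   (kind `accel_mL_per_s2`), both on the input grid.
#' @export
flow_and_acceleration <- function(volume, opts = lv_options()) {
  stopifnot(inherits(volume, "lv_trace"))
  if (length(volume$t) < 3L) stop("insufficient data: need at least 3 samples")
  vs <- smooth_ma(volume$v, opts$smooth_window)
  q <- num_deriv(volume$t, vs)
  qs <- smooth_ma(q, opts$smooth_window)
  a <- num_deriv(volume$t, qs)
  list(flow = lv_trace(volume$t, q, "flow_mL_per_s"),
       accel = lv_trace(volume$t, a, "accel_mL_per_s2"))
}

#' Diastolic event timings
#'
#' Container for the timings of the key diastolic events, all in seconds:
#' aortic valve closure (AVC), mitral valve opening (MVO), minimum P_LV,
#' peak E-wave flow, A-wave start, peak A-wave flow, mitral valve closure
#' (MVC). `missing_a` flags E/A fusion (single filling wave); A-dependent
#' times are then `NA`.
#'
#' @param t_avc,t_mvo,t_minp,t_peak_e,t_a_start,t_peak_a,t_mvc Event times (s).
#' @param missing_a Logical, `TRUE` when no distinct A wave was found.
#' @return An object of class `lv_events`.
#' @export
lv_events <- function(t_avc = NA_real_, t_mvo, t_minp, t_peak_e,
                      t_a_start = NA_real_, t_peak_a = NA_real_, t_mvc,
                      missing_a = FALSE) {
  ev <- list(t_avc = t_avc, t_mvo = t_mvo, t_minp = t_minp,
             t_peak_e = t_peak_e, t_a_start = t_a_start,
             t_peak_a = t_peak_a, t_mvc = t_mvc, missing_a = missing_a)
  ord <- c(ev$t_avc, ev$t_mvo, ev$t_minp, ev$t_peak_e,
           ev$t_a_start, ev$t_peak_a, ev$t_mvc)
  ord <- ord[!is.na(ord)]
  if (any(diff(ord) < 0)) stop("event times violate the diastolic ordering")
  structure(ev, class = "lv_events")
}

#' @export
print.lv_events <- function(x, ...) {
  cat("<lv_events (s)>\n")
  for (nm in c("t_avc", "t_mvo", "t_minp", "t_peak_e", "t_a_start",
               "t_peak_a", "t_mvc"))
    cat(sprintf("  %-9s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%.4f", x[[nm]]))))
  if (isTRUE(x$missing_a)) cat("  [missing A wave]\n")
  invisible(x)
}

# Local maxima of y (with plateau handling) at least `frac` of the global
# max above baseline; candidates closer than `min_sep` samples are merged,
# keeping the tallest. Returns indices in time order. Internal.
find_peaks <- function(y, frac = 0.1, min_sep = 1L) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  thr <- min(y) + frac * (max(y) - min(y))
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  idx <- idx[y[idx] >= thr]
  if (length(idx) <= 1L || min_sep <= 1L) return(idx)
  keep <- integer(0)
  for (i in idx[order(y[idx], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

# Sub-sample onset of a filling wave: the flow above baseline rises
# quadratically at a smooth wave onset, so sqrt(q) is linear in t; a linear
# fit over the 1-10% rise band extrapolated to zero removes both the
# smoothing-induced early bias and the threshold-induced late bias of a
# plain crossing rule. The 0.5-5% band keeps the fit where the quadratic
# approximation is tight but clear of the smoothing-contaminated first
# samples. Falls back to the last at-threshold sample when the band is too
# short. Returns a time. Internal.
flow_onset <- function(t, q, i_from, i_peak, baseline = 0,
                       thr_frac = 1e-6, lo = 0.005, hi = 0.05) {
  idx <- i_from:i_peak
  qb <- q[idx] - baseline
  qpk <- qb[length(qb)]
  low <- idx[qb <= thr_frac * qpk]
  t_fallback <- if (length(low)) t[max(low)] else t[i_from]
  # widen the fit band above the flow noise floor (high-frequency residual
  # near the search start); at zero noise the band is unchanged
  nw <- seq_len(min(11L, length(idx)))
  res <- (qb - smooth_ma(qb, 3L))[nw]
  sq <- 1.4826 * stats::median(abs(res - stats::median(res))) * sqrt(1.5)
  if (qpk > 0 && sq > 1e-7 * qpk) {
    lo <- min(max(lo, 4 * sq / qpk), 0.3)
    hi <- min(max(hi, 12 * sq / qpk, 2 * lo), 0.6)
  }
  band <- which(qb >= lo * qpk & qb <= hi * qpk)
  # contiguous run on the upstroke, ending nearest the peak
  if (length(band) >= 3L) {
    brk <- c(0L, which(diff(band) > 1L), length(band))
    run <- band[(brk[length(brk) - 1L] + 1L):length(band)]
    if (length(run) >= 3L) {
      x <- t[idx[run]]
      y <- sqrt(qb[run])
      c1 <- stats::cov(x, y) / stats::var(x)
      if (is.finite(c1) && c1 > 0) {
        t0 <- mean(x) - mean(y) / c1
        if (t0 >= t[i_from] - (t[2L] - t[1L]) && t0 <= x[1L])
          return(max(t0, t[i_from]))
      }
    }
  }
  t_fallback
}

#' Detect diastolic events from volume, flow and acceleration traces
#'
#' Event rules, applied to one cardiac cycle that starts at end-diastole:
#' MVO is the onset of forward transmitral flow before the first filling
#' peak; peak E is the first flow maximum after MVO; the A start is the end
#' of the low-flow plateau (diastasis) between the two filling peaks; peak A
#' is the second flow maximum; MVC is the end of the cycle. The minimum-P_LV
#' time is placed at the maximum flow acceleration on the E upstroke
#' (`opts$minp_rule`). Onsets are located by walking back from the relevant
#' peak to the last sample below `opts$q_onset_frac` of the diastolic flow
#' maximum (above the local plateau level for the A wave), which recovers
#' noise-free onsets to within one sample.
#'
#' A single filling wave (E/A fusion) sets `missing_a = TRUE` with the
#' A-dependent events `NA`. A minimum two-sample separation is enforced
#' between consecutive events, keeping the earlier event fixed.
#'
#' @param volume,flow,accel Traces from [gls_to_volume()] and
#'   [flow_and_acceleration()].
#' @param opts Options from [lv_options()].
#' @return An [lv_events()] object (with `t_avc = NA`; see [measure_ivrt()]).
#' @export
detect_events <- function(volume, flow, accel, opts = lv_options()) {
  stopifnot(inherits(volume, "lv_trace"), inherits(flow, "lv_trace"),
            inherits(accel, "lv_trace"))
  t <- flow$t; q <- flow$v
  n <- length(t)
  dt <- trace_dt(flow)
  # end-systole: last sample of the minimum-volume plateau
  vmin <- min(volume$v)
  tolv <- 1e-9 * max(diff(range(volume$v)), 1) + 1e-12
  i_es <- max(which(volume$v <= vmin + tolv))
  if (i_es >= n - 2L) stop("detection error: no diastole after minimum volume")
  dia <- i_es:n
  qmax <- max(q[dia])
  if (qmax <= 0) stop("detection error: no filling upstroke found")

  # peak finding on an extra-smoothed flow (noise spikes otherwise masquerade
  # as filling waves); onset fits below stay on the lightly smoothed flow
  qd <- smooth_ma(q, max(opts$smooth_window, 5L))
  sep <- max(2L, as.integer(round(0.06 / dt)))  # E and A peaks > 60 ms apart
  pk_rel <- find_peaks(qd[dia], frac = opts$peak_frac, min_sep = sep)
  pk <- dia[1] - 1L + pk_rel
  pk <- pk[qd[pk] > 0]
  if (length(pk) == 0L) stop("detection error: no filling peak found")
  if (length(pk) > 2L) {               # keep the two tallest, in time order
    pk <- sort(pk[order(qd[pk], decreasing = TRUE)][1:2])
  }
  missing_a <- length(pk) < 2L
  i_pe <- pk[1L]

  # MVO: onset of forward flow before the E peak (sub-sample)
  t_mvo <- flow_onset(t, q, i_es, i_pe, baseline = 0,
                      thr_frac = opts$q_onset_frac)

  # minimum-P_LV time: maximum flow acceleration on the E upstroke
  ups <- which(t >= t_mvo & t <= t[i_pe])
  if (!length(ups)) ups <- i_es:i_pe
  i_minp <- ups[which.max(accel$v[ups])]

  t_as <- t_pa <- NA_real_
  if (!missing_a) {
    i_pa <- pk[2L]
    mid <- (i_pe + 1L):(i_pa - 1L)
    if (length(mid) < 2L) {
      missing_a <- TRUE
    } else {
      qfloor <- min(qd[mid])
      t_as <- flow_onset(t, q, i_pe, i_pa, baseline = qfloor,
                         thr_frac = opts$q_onset_frac)
      t_pa <- t[i_pa]
    }
  }

  # enforce minimum two-sample separation, earlier event kept fixed
  ev <- c(t_mvo, t[i_minp], t[i_pe], t_as, t_pa)
  keep <- !is.na(ev)
  tv <- ev[keep]
  for (k in seq_along(tv)[-1]) {
    if (tv[k] < tv[k - 1L] + 2 * dt) tv[k] <- tv[k - 1L] + 2 * dt
  }
  tv <- pmin(tv, t[n] - dt)
  ev[keep] <- tv

  lv_events(t_mvo = ev[1L], t_minp = ev[2L], t_peak_e = ev[3L],
            t_a_start = ev[4L], t_peak_a = ev[5L],
            t_mvc = t[n], missing_a = missing_a)
}

# AVC surrogate time from the strain trace; internal.
#
# Default rule: first sample of the peak-shortening plateau. Under noise a
# plain argmin wanders the whole isovolumic plateau, so the plateau
# tolerance is scaled to the high-frequency noise level (MAD of the raw
# minus 3-sample-smoothed residual near the minimum); at zero noise the
# estimate collapses to a floating-point floor and the rule is exact.
detect_avc <- function(strain, opts = lv_options()) {
  g <- strain$v; t <- strain$t
  n <- length(g)
  if (identical(opts$avc_rule, "strain_rate_zero")) {
    r <- num_deriv(t, smooth_ma(g, opts$smooth_window))
    gmin <- min(g)
    deep <- which(g <= 0.5 * gmin)       # past half of peak shortening
    cand <- deep[r[deep] >= 0]
    if (length(cand) == 0L) return(t[which.min(g)])
    return(t[cand[1L]])
  }
  i_min <- which.min(g)
  rng <- max(diff(range(g)), 1)
  # noise level from the high-frequency residual inside the plateau (to the
  # right of the minimum, clear of the curved descending edge)
  win <- (i_min + 2L):min(n, i_min + 12L)
  win <- win[win >= 1L & win <= n]
  res <- (g - smooth_ma(g, 3L))[win]
  sigma <- 1.4826 * stats::median(abs(res - stats::median(res))) * sqrt(1.5)
  if (sigma <= 1e-7 * rng) {
    # clean trace: exact plateau-start rule
    tolg <- 1e-9 * rng + 1e-12
    return(t[which(g <= min(g) + tolg)[1L]])
  }
  w <- max(opts$smooth_window, 5L)
  gs <- smooth_ma(g, w)
  tolg <- 3 * sigma / sqrt(w)
  t[which(gs <= min(gs) + tolg)[1L]]
}

#' Isovolumic relaxation time from strain and flow traces
#'
#' IVRT = t_MVO - t_AVC. AVC is taken from the strain trace (peak negative
#' GLS by default, strain-rate zero crossing via `opts$avc_rule`); MVO is
#' the forward-flow onset before the first filling peak, as in
#' [detect_events()].
#'
#' @param strain An [lv_trace()] of kind `strain_pct` covering systole and
#'   early diastole.
#' @param flow A flow trace (kind `flow_mL_per_s`) on the same cycle.
#' @param opts Options from [lv_options()].
#' @return IVRT in seconds (positive).
#' @export
measure_ivrt <- function(strain, flow, opts = lv_options()) {
  stopifnot(inherits(strain, "lv_trace"), inherits(flow, "lv_trace"))
  t_avc <- detect_avc(strain, opts)
  t <- flow$t; q <- flow$v
  after <- which(t > t_avc)
  if (length(after) < 3L) stop("event-order error: no flow data after AVC")
  qmax <- max(q[after])
  if (qmax <= 0) stop("detection error: no filling upstroke after AVC")
  dt <- trace_dt(flow)
  qd <- smooth_ma(q, max(opts$smooth_window, 5L))
  sep <- max(2L, as.integer(round(0.06 / dt)))
  pk_rel <- find_peaks(qd[after], frac = opts$peak_frac, min_sep = sep)
  i_pe <- if (length(pk_rel)) after[pk_rel[1L]] else after[which.max(qd[after])]
  t_mvo <- flow_onset(t, q, after[1L], i_pe, baseline = 0,
                      thr_frac = opts$q_onset_frac)
  ivrt <- t_mvo - t_avc
  if (ivrt <= 0) stop("event-order error: AVC at or after MVO")
  ivrt
}
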