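# Event names delimiting the diastolic curve, in order MVO -> MVC.
curve_event_names <- c("mvo", "minp", "peak_e", "a_start", "peak_a", "mvc")

# Extract the six curve event times from an lv_events object; internal.
curve_event_times <- function(events) {
  c(mvo = events$t_mvo, minp = events$t_minp, peak_e = events$t_peak_e,
    a_start = events$t_a_start, peak_a = events$t_peak_a,
    mvc = events$t_mvc)
}

#' Annotated measured pressure curve
#'
#' Pairs a measured LV pressure trace with the timings of the key diastolic
#' events, as needed to build the time-normalized reference curve.
#'
#' @param trace An [lv_trace()] of kind `pressure_mmHg` spanning diastole.
#' @param events An [lv_events()] whose curve events (MVO through MVC) lie
#'   inside the trace span.
#' @return An `annotated_curve` list.
#' @export
annotated_curve <- function(trace, events) {
  stopifnot(inherits(trace, "lv_trace"), inherits(events, "lv_events"))
  if (trace$kind != "pressure_mmHg") stop("trace must have kind 'pressure_mmHg'")
  et <- curve_event_times(events)
  if (!anyNA(et)) {
    rng <- range(trace$t)
    if (any(et < rng[1] - 1e-9) || any(et > rng[2] + 1e-9))
      stop("event times must lie inside the trace span")
  }
  structure(list(trace = trace, events = events), class = "annotated_curve")
}

#' Build the time-normalized reference diastolic pressure curve
#'
#' Each source curve is cut at its diastolic events (MVO, minimum P_LV,
#' peak E, A start, peak A, MVC); every inter-event segment is resampled by
#' piecewise-linear interpolation onto a common fraction grid in [0, 1] of
#' `n_per_segment` points; the reference is the pointwise mean across
#' curves, with anchor pressures the means at the events. Curves with
#' missing events are excluded with a warning.
#'
#' @param curves List of [annotated_curve()] objects (>= 1 usable).
#' @param n_per_segment Points per normalized segment (default from
#'   [lv_options()]).
#' @return An object of class `lv_reference`: `fraction` (grid), `segments`
#'   (list of 5 mean-pressure vectors, MVO->minP, minP->peakE, peakE->Astart,
#'   Astart->peakA, peakA->MVC), `anchors` (named mmHg at the six events),
#'   `n_sources`.
#' @export
build_reference <- function(curves, n_per_segment = lv_options()$n_per_segment) {
  if (!length(curves)) stop("no curves supplied")
  f <- seq(0, 1, length.out = n_per_segment)
  nseg <- length(curve_event_names) - 1L
  acc <- vector("list", nseg)
  used <- 0L
  for (cv in curves) {
    stopifnot(inherits(cv, "annotated_curve"))
    et <- curve_event_times(cv$events)
    if (anyNA(et)) {
      warning("curve with missing events excluded from the reference")
      next
    }
    used <- used + 1L
    for (k in seq_len(nseg)) {
      tk <- et[k] + f * (et[k + 1L] - et[k])
      pk <- stats::approx(cv$trace$t, cv$trace$v, xout = tk, rule = 2)$y
      acc[[k]] <- if (is.null(acc[[k]])) pk else acc[[k]] + pk
    }
  }
  if (used == 0L) stop("no usable curves: all sources had missing events")
  segments <- lapply(acc, function(s) s / used)
  anchors <- c(vapply(segments, function(s) s[1L], numeric(1)),
               segments[[nseg]][n_per_segment])
  names(anchors) <- curve_event_names
  structure(list(fraction = f, segments = segments, anchors = anchors,
                 n_sources = used),
            class = "lv_reference")
}

#' Per-event anchor pressures for curve generation
#'
#' Maps the solver output to the pressure at each diastolic event:
#' MVO = P_MVO (pre-A + 5 mmHg); minimum P_LV as estimated; peak E =
#' pre-A minus the instantaneous convective gradient at peak E velocity
#' (`dp_at_peak_e`, where temporal acceleration vanishes); A start = pre-A;
#' MVC = EDP (falling back to pre-A + max_dp_a, with a warning, when EDP is
#' unavailable); peak A = midpoint of the A-start and MVC pressures
#' (`opts$peak_a_rule`).
#'
#' @param estimates An `lv_estimates` object from [solve_coupled()] (its
#'   `edp` field set via [estimate_edp()] when available).
#' @param dp_at_peak_e Instantaneous transmitral gradient at peak E
#'   velocity, mmHg (default 0).
#' @param max_dp_a A-wave gradient used in the MVC fallback, mmHg.
#' @param opts Options from [lv_options()].
#' @return Named numeric vector over `mvo, minp, peak_e, a_start, peak_a,
#'   mvc`, with attribute `ordering_warning` set when the anchors violate
#'   ordering sanity (e.g. min P_LV above pre-A).
#' @export
event_pressure_table <- function(estimates, dp_at_peak_e = 0,
                                 max_dp_a = NA_real_, opts = lv_options()) {
  stopifnot(inherits(estimates, "lv_estimates"))
  pre_a <- estimates$pre_a
  mvc <- estimates$edp
  if (is.na(mvc)) {
    fallback <- if (is.na(max_dp_a)) 0 else max_dp_a
    warning("EDP unavailable; MVC anchor falls back to pre-A + max_dp_a")
    mvc <- pre_a + fallback
  }
  peak_a <- switch(opts$peak_a_rule,
                   midpoint = (pre_a + mvc) / 2,
                   stop("unknown peak_a_rule: ", opts$peak_a_rule))
  anchors <- c(mvo = estimates$p_mvo, minp = estimates$min_plv,
               peak_e = pre_a - dp_at_peak_e, a_start = pre_a,
               peak_a = peak_a, mvc = mvc)
  warn <- anchors["minp"] > anchors["a_start"] ||
    anchors["mvo"] < anchors["minp"] || anchors["mvc"] < anchors["a_start"]
  if (isTRUE(warn)) {
    warning("anchor pressures violate the expected diastolic ordering")
    attr(anchors, "ordering_warning") <- TRUE
  }
  anchors
}

#' Generate a patient-specific diastolic pressure curve
#'
#' Starting from the time-normalized reference, the pressure in each
#' segment is shifted by the linear-in-fraction blend of the offsets at its
#' two bounding events (offset = patient anchor - reference anchor), which
#' preserves the reference shape between anchors while passing exactly
#' through the patient's anchor pressures. The fraction grid of each
#' segment is then mapped onto absolute time between the patient's event
#' times and the assembled curve is resampled to a uniform grid of step
#' `dt_s`.
#'
#' @param ref An `lv_reference` from [build_reference()].
#' @param events Patient [lv_events()] (complete curve events).
#' @param event_pressures Named anchor pressures from
#'   [event_pressure_table()].
#' @param dt_s Output sampling step, s (default from [lv_options()]).
#' @return An [lv_trace()] of kind `pressure_mmHg` spanning MVO to MVC.
#' @export
generate_patient_curve <- function(ref, events, event_pressures,
                                   dt_s = lv_options()$curve_dt_s) {
  stopifnot(inherits(ref, "lv_reference"), inherits(events, "lv_events"))
  et <- curve_event_times(events)
  if (anyNA(et)) stop("complete curve events required (no missing A wave)")
  if (!all(curve_event_names %in% names(event_pressures)))
    stop("event_pressures must be named over: ",
         paste(curve_event_names, collapse = ", "))
  offs <- event_pressures[curve_event_names] - ref$anchors
  f <- ref$fraction
  tt <- numeric(0); pp <- numeric(0)
  for (k in seq_along(ref$segments)) {
    pk <- ref$segments[[k]] + (1 - f) * offs[k] + f * offs[k + 1L]
    tk <- et[k] + f * (et[k + 1L] - et[k])
    if (k > 1L) { tk <- tk[-1L]; pk <- pk[-1L] }  # drop duplicated joint
    tt <- c(tt, tk); pp <- c(pp, pk)
  }
  n_out <- max(8L, round((et["mvc"] - et["mvo"]) / dt_s) + 1L)
  grid <- seq(unname(et["mvo"]), unname(et["mvc"]), length.out = n_out)
  out <- stats::approx(tt, pp, xout = grid, rule = 2)$y
  lv_trace(grid, out, "pressure_mmHg")
}

#' Mean diastolic pressure from MVO to MVC
#'
#' Time average (trapezoidal) of a pressure curve over the filling period.
#' Window ends are interpolated when they fall between samples.
#'
#' @param curve An [lv_trace()] of kind `pressure_mmHg`.
#' @param t_mvo,t_mvc Window bounds, s, inside the curve span.
#' @return Mean pressure in mmHg.
#' @export
mean_diastolic_pressure <- function(curve, t_mvo, t_mvc) {
  stopifnot(inherits(curve, "lv_trace"))
  if (!(t_mvo < t_mvc)) stop("t_mvo must be < t_mvc")
  rng <- range(curve$t)
  if (t_mvo < rng[1] - 1e-9 || t_mvc > rng[2] + 1e-9)
    stop("window outside the curve span")
  inner <- curve$t[curve$t > t_mvo & curve$t < t_mvc]
  tt <- c(t_mvo, inner, t_mvc)
  pp <- stats::approx(curve$t, curve$v, xout = tt, rule = 2)$y
  trapz(tt, pp) / (t_mvc - t_mvo)
}
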