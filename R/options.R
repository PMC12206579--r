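#' Analysis options and model constants
#'
#' Central registry of every tunable constant in the pipeline, with defaults
#' matching the published method. Pass the returned list to any function that
#' accepts an `opts` argument, overriding fields as needed.
#'
#' @param ... Named overrides of any default listed below.
#'
#' @details
#' Model constants:
#' \describe{
#'   \item{`tau_ivrt_factor`}{Fraction of IVRT attributed to the exponential
#'     pressure decay (default 0.85; aortic valve closure precedes the onset
#'     of the decay at peak negative dP/dt).}
#'   \item{`p0_fraction`}{Pressure at decay onset as a fraction of systolic
#'     pressure (default 0.65, cohort-derived).}
#'   \item{`p_mvo_offset_mmHg`}{P_LV at mitral valve opening minus mean left
#'     atrial pressure (default 5 mmHg).}
#'   \item{`rho_kg_m3`}{Blood density (default 1060 kg/m^3).}
#'   \item{`pa_per_mmHg`}{Unit conversion, fixed at 133.322 Pa/mmHg.}
#' }
#' Numerical/detection settings:
#' \describe{
#'   \item{`smooth_window`}{Centred moving-average window (samples) applied
#'     before each numerical differentiation (default 3; 1 disables).}
#'   \item{`q_onset_frac`}{Relative flow threshold (fraction of peak diastolic
#'     flow) used when locating wave onsets (default 1e-6; raise for noisy
#'     traces).}
#'   \item{`peak_frac`}{Minimum height of a filling-wave peak relative to the
#'     tallest diastolic peak (default 0.1).}
#'   \item{`avc_rule`}{Aortic-valve-closure surrogate from the strain trace:
#'     `"strain_min"` (peak negative GLS, default) or `"strain_rate_zero"`.}
#'   \item{`minp_rule`}{Placement of the minimum-pressure time: `"accel_max"`
#'     (time of maximum dQ/dt on the E upstroke, default).}
#'   \item{`dq_rule`}{Flow-increment convention in the transmitral gradient:
#'     `"onset"` (Q(t) - Q(wave onset), default), `"fixed"` (per-wave
#'     Q_peak - Q_onset) or `"diff"` (per-sample difference).}
#'   \item{`dq_floor_frac`}{Floor on |dQ| as a fraction of the window's peak
#'     |Q|, preventing blow-up near the onset (default 0.05).}
#'   \item{`solver_tol_mmHg`, `solver_max_iter`, `init_pre_a_mmHg`}{Coupled
#'     fixed-point solver: convergence tolerance (0.01 mmHg), iteration cap
#'     (10), starting pre-A pressure (10 mmHg).}
#'   \item{`n_per_segment`, `curve_dt_s`}{Reference-curve resolution (100
#'     points per inter-event segment) and output sampling step (5 ms).}
#'   \item{`orifice_cm2`}{Effective mitral orifice area mapping flow rate to
#'     velocity (default 4 cm^2).}
#'   \item{`peak_a_rule`}{Anchor pressure at peak A: `"midpoint"` between the
#'     A-start and MVC pressures (default).}
#'   \item{`passive_rise_mmHg`}{Passive-filling pressure rise added to the
#'     end-diastolic pressure (default 0; pluggable).}
#' }
#'
#' @return A named list of options (class `lv_options`).
#' @export
#' @examples
#' opts <- lv_options(smooth_window = 5)
#' opts$rho_kg_m3
lv_options <- function(...) {
  opts <- list(
    tau_ivrt_factor  = 0.85,
    p0_fraction      = 0.65,
    p_mvo_offset_mmHg = 5,
    rho_kg_m3        = 1060,
    pa_per_mmHg      = 133.322,
    smooth_window    = 3L,
    q_onset_frac     = 1e-6,
    peak_frac        = 0.1,
    avc_rule         = "strain_min",
    minp_rule        = "accel_max",
    dq_rule          = "onset",
    dq_floor_frac    = 0.05,
    solver_tol_mmHg  = 0.01,
    solver_max_iter  = 10L,
    init_pre_a_mmHg  = 10,
    n_per_segment    = 100L,
    curve_dt_s       = 0.005,
    orifice_cm2      = 4,
    peak_a_rule      = "midpoint",
    passive_rise_mmHg = 0
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(opts))
    if (length(bad)) stop("unknown option(s): ", paste(bad, collapse = ", "))
    opts[names(over)] <- over
  }
  structure(opts, class = "lv_options")
}

#' Read options from a JSON configuration file
#'
#' Loads a flat JSON object of option overrides and merges it over the
#' defaults of [lv_options()]. Unknown keys are an error, so typos in a config
#' file are caught early.
#'
#' @param path Path to a JSON file.
#' @return An `lv_options` list.
#' @export
lv_options_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(lv_options, as.list(raw))
}
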