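# Expected unit strings for the scalar fields of a patient manifest.
expected_units <- c(psys = "mmHg", bmi = "kg/m2", lars = "%",
                    edv = "mL", esv = "mL", hr = "bpm")

#' Load a patient record from a manifest JSON
#'
#' Manifest schema (paths relative to the manifest's directory):
#' \preformatted{
#' {
#'   "id": "p001",
#'   "scalars": {"psys": 120, "bmi": 25, "lars": 35,
#'               "edv": 120, "esv": 50, "hr": 60},
#'   "units":   {"psys": "mmHg", "bmi": "kg/m2", "lars": "%",
#'               "edv": "mL", "esv": "mL", "hr": "bpm"},
#'   "traces":  {"strain": "p001_strain.csv",
#'               "velocity": "p001_velocity.csv"},
#'   "reference_pressure": "p001_pressure.csv"
#' }
#' }
#' `units`, `traces$velocity` and `reference_pressure` are optional; units,
#' when present, are validated against the expected strings and a mismatch
#' is reported with the offending field name.
#'
#' @param path Path to the manifest JSON file.
#' @return A `patient_record` list: `id`, `scalars`, `strain`, `velocity`
#'   (or `NULL`), `reference_pressure` (or `NULL`).
#' @export
load_patient <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  if (is.null(man$id)) stop("manifest parse error: missing field 'id'")
  sc <- man$scalars
  for (nm in c("psys", "bmi", "lars", "edv", "esv", "hr"))
    if (is.null(sc[[nm]]) || !is.numeric(sc[[nm]]))
      stop("manifest parse error: missing or non-numeric scalar '", nm, "'")
  if (!is.null(man$units)) {
    for (nm in names(man$units)) {
      if (!nm %in% names(expected_units))
        stop("manifest parse error: unknown unit field '", nm, "'")
      if (!identical(man$units[[nm]], unname(expected_units[nm])))
        stop(sprintf(
          "manifest parse error: field '%s' has unit '%s', expected '%s'",
          nm, man$units[[nm]], expected_units[nm]))
    }
  }
  if (is.null(man$traces$strain))
    stop("manifest parse error: missing field 'traces.strain'")
  strain <- read_trace_csv(file.path(dir, man$traces$strain), "strain_pct")
  velocity <- NULL
  if (!is.null(man$traces$velocity))
    velocity <- read_trace_csv(file.path(dir, man$traces$velocity),
                               "velocity_m_per_s")
  refp <- NULL
  if (!is.null(man$reference_pressure))
    refp <- read_trace_csv(file.path(dir, man$reference_pressure),
                           "pressure_mmHg")
  structure(list(id = man$id, scalars = as.list(sc[c("psys", "bmi", "lars",
                                                     "edv", "esv", "hr")]),
                 strain = strain, velocity = velocity,
                 reference_pressure = refp),
            class = "patient_record")
}

#' Save a patient record as manifest JSON plus trace CSVs
#'
#' Inverse of [load_patient()]; round-trips exactly up to CSV numeric
#' formatting.
#'
#' @param record A `patient_record`.
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
save_patient <- function(record, dir) {
  stopifnot(inherits(record, "patient_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record$id
  traces <- list(strain = sprintf("%s_strain.csv", id))
  write_trace_csv(record$strain, file.path(dir, traces$strain))
  if (!is.null(record$velocity)) {
    traces$velocity <- sprintf("%s_velocity.csv", id)
    write_trace_csv(record$velocity, file.path(dir, traces$velocity))
  }
  man <- list(id = id, scalars = record$scalars,
              units = as.list(expected_units), traces = traces)
  if (!is.null(record$reference_pressure)) {
    man$reference_pressure <- sprintf("%s_pressure.csv", id)
    write_trace_csv(record$reference_pressure,
                    file.path(dir, man$reference_pressure))
  }
  path <- file.path(dir, sprintf("%s.json", id))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Convert a synthetic patient to a patient record
#'
#' @param patient An `lv_synth_patient` from [simulate_patient()].
#' @return A `patient_record` consumable by [run_estimate()].
#' @export
as_patient_record <- function(patient) {
  stopifnot(inherits(patient, "lv_synth_patient"))
  structure(list(id = patient$id, scalars = patient$scalars,
                 strain = patient$traces$strain,
                 velocity = patient$traces$velocity,
                 reference_pressure = patient$traces$pressure),
            class = "patient_record")
}

#' Write a synthetic cohort to a directory
#'
#' Emits one manifest JSON plus trace CSVs per patient and a cohort
#' manifest CSV of the true parameters.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (pt in cohort) save_patient(as_patient_record(pt), dir)
  utils::write.csv(attr(cohort, "manifest"),
                   file.path(dir, "cohort_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Run the full estimation pipeline on one patient record
#'
#' Pipeline: strain -> volume ([gls_to_volume()]) -> flow/acceleration ->
#' event detection and IVRT -> per-wave transmitral gradient maxima ->
#' coupled solver ([solve_coupled()]) -> EDP. When no measured velocity
#' trace is present, transmitral velocity is derived from the flow trace
#' through the effective orifice area (`opts$orifice_cm2`). With a fused
#' E/A wave the A-dependent outputs (EDP) are `NA` and the rest is
#' computed.
#'
#' @param record A `patient_record` from [load_patient()],
#'   [as_patient_record()], or built in code.
#' @param model A [min_plv_model()].
#' @param opts Options from [lv_options()].
#' @return An `lv_estimates` object with additional fields `id`, `events`
#'   (detected [lv_events()] including AVC) and `diagnostics` (IVRT, wave
#'   gradients, solver iterations).
#' @export
#' @examples
#' pt <- simulate_patient(sim_params(seed = 3))
#' est <- run_estimate(as_patient_record(pt))
#' c(est$tau, pt$true$tau)
run_estimate <- function(record, model = min_plv_model(),
                         opts = lv_options()) {
  stopifnot(inherits(record, "patient_record"))
  sc <- record$scalars
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  volume <- stage("kinematics", gls_to_volume(record$strain, sc$edv, sc$esv))
  fa <- stage("kinematics", flow_and_acceleration(volume, opts))
  ev <- stage("events", detect_events(volume, fa$flow, fa$accel, opts))
  ivrt_s <- stage("ivrt", measure_ivrt(record$strain, fa$flow, opts))
  ev$t_avc <- ev$t_mvo - ivrt_s
  velocity <- record$velocity
  if (is.null(velocity))
    velocity <- lv_trace(fa$flow$t,
                         pmax(fa$flow$v, 0) / (opts$orifice_cm2 * 100),
                         "velocity_m_per_s")
  e_end <- if (ev$missing_a) ev$t_mvc else ev$t_a_start
  mde <- stage("gradient",
               max_dp_over_wave(velocity, fa$flow,
                                wave_window(ev$t_mvo, e_end, "E"), opts))
  mda <- list(dp_mmHg = NA_real_)
  if (!ev$missing_a)
    mda <- stage("gradient",
                 max_dp_over_wave(velocity, fa$flow,
                                  wave_window(ev$t_a_start, ev$t_mvc, "A"),
                                  opts))
  scal <- stage("solver",
                patient_scalars(sc$psys, sc$bmi, sc$lars, 1000 * ivrt_s,
                                mde$dp_mmHg, mda$dp_mmHg,
                                opts$passive_rise_mmHg))
  est <- stage("solver", solve_coupled(scal, model, opts))
  est$edp <- estimate_edp(est$pre_a, mda$dp_mmHg, opts$passive_rise_mmHg)
  est$id <- record$id
  est$events <- ev
  est$diagnostics <- list(ivrt_ms = 1000 * ivrt_s, max_dp_e = mde$dp_mmHg,
                          max_dp_a = mda$dp_mmHg,
                          iterations = est$iterations,
                          converged = est$converged,
                          missing_a = ev$missing_a)
  est
}

#' Serialize estimates (with diagnostics and resolved options) to JSON
#'
#' @param est An `lv_estimates` object from [run_estimate()] or
#'   [solve_coupled()].
#' @param path Output JSON path.
#' @param opts The options used, embedded for provenance.
#' @return `path`, invisibly.
#' @export
write_estimates_json <- function(est, path, opts = lv_options()) {
  out <- list(id = est$id, tau_ms = est$tau, min_plv_mmHg = est$min_plv,
              pre_a_mmHg = est$pre_a, p_mvo_mmHg = est$p_mvo,
              edp_mmHg = est$edp, iterations = est$iterations,
              converged = est$converged, diagnostics = est$diagnostics,
              options = unclass(opts))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
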