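#' Uniformly sampled physiological trace
#'
#' The basic container used throughout the package: a time series on a
#' strictly increasing, uniform time grid. Kinds carry the unit convention:
#' `strain_pct` (GLS, negative at end-systole), `volume_mL`, `flow_mL_per_s`,
#' `accel_mL_per_s2`, `velocity_m_per_s`, `pressure_mmHg`.
#'
#' @param t Numeric vector of sample times in seconds (uniform grid,
#'   strictly increasing, length >= 8).
#' @param v Numeric vector of values, same length as `t`, no missing values.
#' @param kind One of the kind strings above.
#' @return An object of class `lv_trace` with fields `t`, `v`, `kind`.
#' @export
#' @examples
#' tr <- lv_trace(seq(0, 1, by = 0.01), sin(seq(0, 1, by = 0.01)),
#'                "pressure_mmHg")
#' trace_dt(tr)
lv_trace <- function(t, v, kind) {
  kinds <- c("strain_pct", "volume_mL", "flow_mL_per_s", "accel_mL_per_s2",
             "velocity_m_per_s", "pressure_mmHg")
  kind <- match.arg(kind, kinds)
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(t) != length(v)) stop("t and v must have equal length")
  if (length(t) < 8L) stop("trace too short: need at least 8 samples")
  if (anyNA(t) || anyNA(v) || any(!is.finite(v)))
    stop("trace contains missing or non-finite values")
  dts <- diff(t)
  if (any(dts <= 0)) stop("time grid must be strictly increasing")
  dt <- mean(dts)
  if (max(abs(dts - dt)) / dt > 1e-9)
    stop("time grid must be uniform (relative tolerance 1e-9)")
  structure(list(t = t, v = v, kind = kind), class = "lv_trace")
}

#' @export
print.lv_trace <- function(x, ...) {
  cat(sprintf("<lv_trace %s: %d samples, t = [%.4g, %.4g] s, dt = %.4g s>\n",
              x$kind, length(x$t), x$t[1], x$t[length(x$t)], trace_dt(x)))
  invisible(x)
}

#' Sampling interval of a trace
#'
#' @param trace An [lv_trace()].
#' @return Sampling step in seconds.
#' @export
trace_dt <- function(trace) {
  stopifnot(inherits(trace, "lv_trace"))
  (trace$t[length(trace$t)] - trace$t[1]) / (length(trace$t) - 1L)
}

#' Read a trace from a two-column CSV file
#'
#' Expects a header `time_s,value` (UTF-8, decimal point). The trace kind is
#' taken from `kind` if given, otherwise inferred from the file name: the
#' last of `strain`, `volume`, `flow`, `velocity`, `pressure` appearing in
#' the base name selects the corresponding kind.
#'
#' @param path CSV file path.
#' @param kind Optional explicit kind (see [lv_trace()]).
#' @return An `lv_trace`.
#' @export
read_trace_csv <- function(path, kind = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace CSV must have columns 'time_s' and 'value': ", path)
  if (is.null(kind)) {
    base <- tolower(basename(path))
    map <- c(strain = "strain_pct", volume = "volume_mL",
             flow = "flow_mL_per_s", velocity = "velocity_m_per_s",
             pressure = "pressure_mmHg")
    hit <- names(map)[vapply(names(map), grepl, logical(1), x = base,
                             fixed = TRUE)]
    if (length(hit) == 0L)
      stop("cannot infer trace kind from file name: ", basename(path))
    kind <- unname(map[hit[length(hit)]])
  }
  lv_trace(df$time_s, df$value, kind)
}

#' Write a trace to a two-column CSV file
#'
#' @param trace An [lv_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "lv_trace"))
  utils::write.csv(data.frame(time_s = trace$t, value = trace$v),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Restrict a trace to [t0, t1]; internal.
trace_window <- function(trace, t0, t1) {
  sel <- trace$t >= t0 - 1e-12 & trace$t <= t1 + 1e-12
  list(t = trace$t[sel], v = trace$v[sel])
}

# Centred moving average with shrinking windows at the edges; window = 1
# (or NULL) is the identity. Internal.
smooth_ma <- function(v, window) {
  if (is.null(window) || window <= 1L) return(v)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  h <- window %/% 2L
  n <- length(v)
  out <- v
  cs <- cumsum(c(0, v))
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

# Central-difference derivative (one-sided at the ends); internal.
num_deriv <- function(t, v) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  d[1L] <- (v[2L] - v[1L]) / (t[2L] - t[1L])
  d[n] <- (v[n] - v[n - 1L]) / (t[n] - t[n - 1L])
  d
}

# Trapezoidal integral; internal.
trapz <- function(t, v) sum(diff(t) * (v[-1] + v[-length(v)])) / 2
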