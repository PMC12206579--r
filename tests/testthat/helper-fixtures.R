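# Shared fixtures, built in code.

# A clean single-filling-wave volume trace (no A wave), one cycle.
single_wave_volume <- function(dt = 0.002, esv = 50, edv = 120,
                               t_avc = 0.32, t_mvo = 0.40, d_e = 0.45) {
  t <- seq(0, 1, by = dt)
  v <- numeric(length(t))
  v[t <= t_avc] <- esv + (edv - esv) * (1 + cos(pi * t[t <= t_avc] / t_avc)) / 2
  v[t > t_avc] <- esv
  ine <- t > t_mvo & t <= t_mvo + d_e
  s <- (t[ine] - t_mvo) / d_e
  v[ine] <- esv + (edv - esv) * (s - sin(2 * pi * s) / (2 * pi))
  v[t > t_mvo + d_e] <- edv
  lv_trace(t, v, "volume_mL")
}

# Default zero-noise synthetic patient used across tests.
default_patient <- function(seed = 3, ...) {
  simulate_patient(sim_params(seed = seed, ...))
}

# Independent fixed-point oracle for the coupled solver: scan a fine pre-A
# grid and return the self-consistency minimizer. Deliberately avoids
# solve_coupled / estimate_* internals beyond the published formulas.
solver_oracle <- function(psys, bmi, lars, ivrt_ms, max_dp_e,
                          grid = seq(0, 40, by = 0.001)) {
  p_mvo <- grid + 5
  ok <- p_mvo > 0 & p_mvo < 0.65 * psys
  tau <- 0.85 * ivrt_ms / (log(0.65 * psys) - log(p_mvo))
  minp <- -6.885 + 0.025 * psys + 0.243 * bmi - 0.097 * lars + 0.158 * tau
  f <- minp + max_dp_e
  d <- ifelse(ok, f - grid, NA)
  # first stable crossing (d changes sign + -> -): the physical fixed
  # point; the map also has an unstable upper crossing near the P_MVO
  # singularity
  cross <- which(d[-length(d)] > 0 & d[-1] <= 0)
  if (!length(cross)) return(NA_real_)
  i <- cross[1L]
  grid[c(i, i + 1L)][which.min(abs(d[c(i, i + 1L)]))]
}
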