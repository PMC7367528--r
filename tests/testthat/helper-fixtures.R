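# Shared fixtures: traces built in code, no stored data.

# Pure sinusoid y = mid + A*sin(2*pi*t/period), sampled at rate_hz.
make_sine_trace <- function(n_cycles = 10, period = 6, amplitude = 200,
                            midpoint = 300, rate_hz = 30) {
  t <- seq(0, n_cycles * period, by = 1 / rate_hz)
  motion_trace(t, midpoint + amplitude * sin(2 * pi * t / period))
}

# Smoothing parameters that leave the signal essentially untouched:
# level smoothing off, jitter radius tiny (every deviation passes through),
# deviation clamp huge.
passthrough_smoothing <- function() {
  smoothing_params(smoothing = 0, correction = 0, prediction = 0,
                   jitter_radius_mm = 1e-9, max_deviation_radius_mm = 1e9)
}

default_cal <- function() calibration_profile(100, 500, tolerance_mm = 20)

# Brute-force per-half-cycle extremum times of a sinusoid trace (oracle for
# detect_endpoints): split samples into analytic half-cycles and take the
# argmax/argmin in each.
sine_extrema_oracle <- function(trace, period = 6) {
  t <- trace$time_s
  y <- trace$y_mm
  half <- period / 2
  out <- data.frame(time_s = numeric(), phase_label = character())
  k <- 0
  repeat {
    lo <- k * half
    hi <- lo + half
    idx <- which(t >= lo & t < hi)
    if (length(idx) == 0 || hi > max(t)) break
    is_max <- (k %% 2) == 0            # sin rises first: max in half-cycle 0
    i <- if (is_max) idx[which.max(y[idx])] else idx[which.min(y[idx])]
    out <- rbind(out, data.frame(
      time_s = t[i],
      phase_label = if (is_max) "concentric" else "eccentric"))
    k <- k + 1
  }
  out
}
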