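#' Breath-audio amplitude envelope
#'
#' @param time_s Strictly increasing frame times, seconds.
#' @param amplitude Normalised envelope values in `[0, 1]`.
#' @return An object of class `breath_envelope` (a data.frame).
#' @export
breath_envelope <- function(time_s, amplitude) {
  if (length(time_s) != length(amplitude)) {
    stop_input("time_s and amplitude must have equal length")
  }
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    stop_input("envelope times must be strictly increasing")
  }
  if (length(amplitude) &&
      (any(!is.finite(amplitude)) || any(amplitude < 0) || any(amplitude > 1))) {
    stop_input("amplitude must lie in [0, 1]")
  }
  structure(data.frame(time_s = as.numeric(time_s),
                       amplitude = as.numeric(amplitude)),
            class = c("breath_envelope", "data.frame"))
}

#' Exhalation-detector parameters
#'
#' Hysteresis thresholding of the normalised breath envelope: an exhalation
#' opens when the envelope reaches `on_threshold` and closes when it falls
#' below `off_threshold`; events closer than `min_gap_s` are merged and
#' events shorter than `min_duration_s` discarded.
#'
#' @param window_s RMS window length, seconds.
#' @param on_threshold Envelope level opening an exhalation (0-1).
#' @param off_threshold Envelope level closing it; must be below
#'   `on_threshold`.
#' @param min_duration_s Minimum exhalation length, seconds.
#' @param min_gap_s Minimum silence between distinct exhalations, seconds.
#' @return An object of class `breath_detector_params`.
#' @export
breath_detector_params <- function(window_s = 0.1, on_threshold = 0.2,
                                   off_threshold = 0.1, min_duration_s = 0.3,
                                   min_gap_s = 0.5) {
  check_number(window_s, "window_s", 0, strict_lower = TRUE)
  check_number(on_threshold, "on_threshold", 0, 1, strict_lower = TRUE)
  check_number(off_threshold, "off_threshold", 0, 1)
  if (off_threshold >= on_threshold) {
    stop_input("off_threshold must be below on_threshold")
  }
  check_number(min_duration_s, "min_duration_s", 0, strict_lower = TRUE)
  check_number(min_gap_s, "min_gap_s", 0, strict_lower = TRUE)
  structure(list(window_s = window_s, on_threshold = on_threshold,
                 off_threshold = off_threshold,
                 min_duration_s = min_duration_s, min_gap_s = min_gap_s),
            class = "breath_detector_params")
}

#' Compute a normalised RMS envelope from raw audio samples
#'
#' Causal sliding root-mean-square over `window_s`, evaluated every
#' `hop_s` and stamped at the trailing window edge, then normalised by the
#' global maximum (a 1e-6 noise-floor epsilon keeps all-silent recordings at
#' an all-zero envelope). Normalisation makes the detector thresholds
#' unitless and the detection scale-invariant.
#'
#' @param audio_samples Numeric vector of raw audio samples (mono).
#' @param sample_rate_hz Audio sample rate, Hz.
#' @param window_s RMS window length, seconds.
#' @param hop_s Time step between envelope frames; defaults to half the
#'   window.
#' @return A [breath_envelope()].
#' @export
compute_envelope <- function(audio_samples, sample_rate_hz, window_s = 0.1,
                             hop_s = window_s / 2) {
  if (length(audio_samples) == 0L) stop_input("audio is empty")
  check_number(sample_rate_hz, "sample_rate_hz", 0, strict_lower = TRUE)
  check_number(window_s, "window_s", 0, strict_lower = TRUE)
  w <- max(1L, round(window_s * sample_rate_hz))
  h <- max(1L, round(hop_s * sample_rate_hz))
  n <- length(audio_samples)
  # full windows only: a trailing fragment would distort the normalisation
  starts <- if (n >= w) seq.int(1L, n - w + 1L, by = h) else 1L
  cs <- cumsum(c(0, audio_samples^2))
  ends <- pmin(starts + w - 1L, n)
  rms <- sqrt((cs[ends + 1L] - cs[starts]) / (ends - starts + 1L))
  peak <- max(rms)
  amp <- if (peak > 1e-6) rms / peak else rms * 0
  breath_envelope((ends) / sample_rate_hz, pmin(amp, 1))
}

#' Detect exhalation events in a breath envelope
#'
#' Hysteresis threshold crossings: an event opens at the first frame at or
#' above `on_threshold` and closes at the first subsequent frame below
#' `off_threshold` (an event still open at the end of the recording closes
#' at the final frame). Events separated by less than `min_gap_s` are
#' merged, then events shorter than `min_duration_s` are discarded.
#'
#' @param env A [breath_envelope()].
#' @param params A [breath_detector_params()].
#' @return A data.frame with columns `onset_s` and `offset_s`, one row per
#'   exhalation, time-ordered.
#' @export
detect_exhalations <- function(env, params = breath_detector_params()) {
  stopifnot(inherits(params, "breath_detector_params"))
  t <- env$time_s
  a <- env$amplitude
  onsets <- numeric(); offsets <- numeric()
  open <- FALSE
  onset <- NA_real_
  for (i in seq_along(a)) {
    if (!open && a[i] >= params$on_threshold) {
      open <- TRUE
      onset <- t[i]
    } else if (open && a[i] < params$off_threshold) {
      open <- FALSE
      onsets <- c(onsets, onset); offsets <- c(offsets, t[i])
    }
  }
  if (open) {
    onsets <- c(onsets, onset); offsets <- c(offsets, t[length(t)])
  }
  # merge events separated by less than min_gap_s
  if (length(onsets) > 1L) {
    keep_on <- onsets[1]; keep_off <- offsets[1]
    m_on <- numeric(); m_off <- numeric()
    for (k in 2:length(onsets)) {
      if (onsets[k] - keep_off < params$min_gap_s) {
        keep_off <- offsets[k]
      } else {
        m_on <- c(m_on, keep_on); m_off <- c(m_off, keep_off)
        keep_on <- onsets[k]; keep_off <- offsets[k]
      }
    }
    onsets <- c(m_on, keep_on); offsets <- c(m_off, keep_off)
  }
  ok <- (offsets - onsets) >= params$min_duration_s
  data.frame(onset_s = onsets[ok], offset_s = offsets[ok])
}

#' Count exhalations within a set window
#'
#' Counts events whose onset lies in the half-open interval
#' `[set_start_s, set_end_s)`. Ten exhalations over a 10-repetition set —
#' one per movement cycle — is the instructed breathing rhythm.
#'
#' @param events Output of [detect_exhalations()].
#' @param set_start_s,set_end_s Set window, seconds (`set_end_s` exclusive).
#' @return Integer count.
#' @export
count_exhalations <- function(events, set_start_s, set_end_s) {
  if (set_end_s <= set_start_s) stop_input("set_end_s must exceed set_start_s")
  sum(events$onset_s >= set_start_s & events$onset_s < set_end_s)
}

#' Breathing-pacer brightness
#'
#' Piecewise-linear triangular wave guiding the breathing rhythm: the light
#' ramps from minimum to maximum brightness over `period_up_s` (inhale cue)
#' and back down over `period_down_s` (exhale cue), repeating — 0 to 1 in
#' 3 s and back in 3 s at the defaults, matching the 6 s movement period.
#'
#' @param t Time(s) since set start, seconds (vectorised, `t >= 0`).
#' @param period_up_s,period_down_s Ramp durations, seconds.
#' @return Brightness in `[0, 1]`.
#' @export
pacer_brightness <- function(t, period_up_s = 3, period_down_s = 3) {
  check_number(period_up_s, "period_up_s", 0, strict_lower = TRUE)
  check_number(period_down_s, "period_down_s", 0, strict_lower = TRUE)
  period <- period_up_s + period_down_s
  ph <- t %% period
  ifelse(ph < period_up_s, ph / period_up_s,
         1 - (ph - period_up_s) / period_down_s)
}

#' Breath-hold (Valsalva) monitor
#'
#' Scans the exhalation stream over `[0, horizon_s]` and emits a
#' `lights_off` event exactly `timeout_s` after the reference point of the
#' most recent exhalation (its offset; time 0 before any exhalation)
#' whenever no new exhalation onset intervenes — the darkness cues the
#' exerciser to resume breathing. A `lights_on` event follows at the next
#' exhalation onset. `lights_off`/`lights_on` strictly alternate, starting
#' with `lights_off`.
#'
#' @param events Time-ordered output of [detect_exhalations()].
#' @param horizon_s End of the monitored window, seconds.
#' @param timeout_s Silence duration that triggers lights-off (default 6).
#' @param reference `"offset"` (default) starts the silence timer at the end
#'   of the last exhalation; `"onset"` at its start.
#' @return A `feedback_events` data.frame of `lights_off` / `lights_on`
#'   events.
#' @export
valsalva_monitor <- function(events, horizon_s, timeout_s = 6,
                             reference = c("offset", "onset")) {
  reference <- match.arg(reference)
  check_number(horizon_s, "horizon_s", 0, strict_lower = TRUE)
  check_number(timeout_s, "timeout_s", 0, strict_lower = TRUE)
  out <- new_events()
  on <- TRUE
  ref <- 0
  for (i in seq_len(nrow(events))) {
    onset <- events$onset_s[i]
    if (onset > horizon_s) break
    if (on && onset > ref + timeout_s) {
      out <- rbind(out, new_events(ref + timeout_s, "lights_off"))
      on <- FALSE
    }
    if (!on) {
      out <- rbind(out, new_events(onset, "lights_on"))
      on <- TRUE
    }
    ref <- if (reference == "offset") events$offset_s[i] else onset
  }
  if (on && ref + timeout_s <= horizon_s) {
    out <- rbind(out, new_events(ref + timeout_s, "lights_off"))
  }
  class(out) <- c("feedback_events", "data.frame")
  out
}

#' Light-channel signal over time
#'
#' Combines the pacer waveform with the on/off state from the Valsalva
#' monitor: while the lights are off the brightness is 0; at each
#' `lights_on` event the pacer restarts from minimum brightness.
#'
#' @param times Sample times, seconds.
#' @param light_events Output of [valsalva_monitor()].
#' @param period_up_s,period_down_s Pacer ramp durations, seconds.
#' @return A data.frame `time_s`, `brightness`, `on`.
#' @export
light_signal <- function(times, light_events, period_up_s = 3,
                         period_down_s = 3) {
  on <- rep(TRUE, length(times))
  origin <- rep(0, length(times))   # pacer phase origin per sample
  state_on <- TRUE
  state_origin <- 0
  ev_i <- 1L
  ne <- nrow(light_events)
  for (k in seq_along(times)) {
    while (ev_i <= ne && light_events$time_s[ev_i] <= times[k]) {
      if (light_events$kind[ev_i] == "lights_off") {
        state_on <- FALSE
      } else if (light_events$kind[ev_i] == "lights_on") {
        state_on <- TRUE
        state_origin <- light_events$time_s[ev_i]
      }
      ev_i <- ev_i + 1L
    }
    on[k] <- state_on
    origin[k] <- state_origin
  }
  b <- ifelse(on, pacer_brightness(pmax(times - origin, 0),
                                   period_up_s, period_down_s), 0)
  data.frame(time_s = times, brightness = b, on = on)
}
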