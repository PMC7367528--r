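#' Synthetic exerciser profile
#'
#' Behavioural parameters of a simulated exerciser performing sets of
#' repetitions. The defaults describe the instructed ideal: 3 s concentric
#' and 3 s eccentric half-cycles, 10 repetitions, no pace or range-of-motion
#' error. Setting `con_time_s = 2.17`, `time_jitter_sd_s = 0.72` mimics the
#' pace distribution of unassisted (no-feedback) exercisers; pace and ROM
#' jitter knobs describe within-set, between-repetition variation only.
#'
#' @param con_time_s,ecc_time_s Target lifting / lowering half-cycle
#'   durations, seconds.
#' @param time_jitter_sd_s SD of per-half-cycle duration jitter, seconds.
#' @param rom_bias_mm Systematic offset added to every endpoint target, mm.
#' @param rom_jitter_sd_mm SD of per-endpoint position jitter, mm.
#' @param noise_sd_mm SD of additive white measurement noise per sample, mm.
#' @param n_reps Repetitions per set.
#' @param amplitude_mm,midpoint_mm Movement geometry: endpoints at
#'   `midpoint_mm +/- amplitude_mm`.
#' @return An object of class `exerciser_profile`.
#' @export
exerciser_profile <- function(con_time_s = 3, ecc_time_s = 3,
                              time_jitter_sd_s = 0, rom_bias_mm = 0,
                              rom_jitter_sd_mm = 0, noise_sd_mm = 0,
                              n_reps = 10, amplitude_mm = 200,
                              midpoint_mm = 300) {
  check_number(con_time_s, "con_time_s", 0, strict_lower = TRUE)
  check_number(ecc_time_s, "ecc_time_s", 0, strict_lower = TRUE)
  check_number(time_jitter_sd_s, "time_jitter_sd_s", 0)
  check_number(rom_bias_mm, "rom_bias_mm")
  check_number(rom_jitter_sd_mm, "rom_jitter_sd_mm", 0)
  check_number(noise_sd_mm, "noise_sd_mm", 0)
  check_number(n_reps, "n_reps", 1)
  check_number(amplitude_mm, "amplitude_mm", 0, strict_lower = TRUE)
  check_number(midpoint_mm, "midpoint_mm")
  structure(list(con_time_s = con_time_s, ecc_time_s = ecc_time_s,
                 time_jitter_sd_s = time_jitter_sd_s,
                 rom_bias_mm = rom_bias_mm,
                 rom_jitter_sd_mm = rom_jitter_sd_mm,
                 noise_sd_mm = noise_sd_mm, n_reps = as.integer(n_reps),
                 amplitude_mm = amplitude_mm, midpoint_mm = midpoint_mm),
            class = "exerciser_profile")
}

# Minimum plausible half-cycle; duration jitter is truncated here so traces
# stay detectable.
MIN_HALF_CYCLE_S <- 0.5

#' Generate a synthetic motion trace
#'
#' Builds one set as concatenated half-cycle cosine segments (smooth
#' velocity, zero at the endpoints). Half-cycle durations are drawn from
#' `N(con_time_s, time_jitter_sd_s^2)` / `N(ecc_time_s, ...)` truncated at
#' 0.5 s; endpoint targets are `midpoint +/- amplitude` plus
#' `N(rom_bias_mm, rom_jitter_sd_mm^2)`; white noise
#' `N(0, noise_sd_mm^2)` is added per sample. The set starts and ends at
#' the lowered (eccentric) position. Deterministic given `seed`; the
#' generated endpoint schedule is attached as attribute `"schedule"`.
#'
#' @param profile An [exerciser_profile()].
#' @param rate_hz Sampling rate, Hz (default 30).
#' @param seed Integer seed.
#' @param exercise_kind Exercise label for the trace metadata.
#' @return A [motion_trace()].
#' @export
gen_motion <- function(profile, rate_hz = 30, seed = 1,
                       exercise_kind = "bicep_curl") {
  stopifnot(inherits(profile, "exerciser_profile"))
  check_number(rate_hz, "rate_hz", 0, strict_lower = TRUE)
  with_seed(seed, {
    n_half <- 2L * profile$n_reps
    means <- rep(c(profile$con_time_s, profile$ecc_time_s), profile$n_reps)
    dur <- pmax(stats::rnorm(n_half, means, profile$time_jitter_sd_s),
                MIN_HALF_CYCLE_S)
    tau <- c(0, cumsum(dur))
    lo <- profile$midpoint_mm - profile$amplitude_mm
    hi <- profile$midpoint_mm + profile$amplitude_mm
    targets <- rep(c(hi, lo), profile$n_reps)       # con, ecc, con, ecc, ...
    v <- c(lo, targets) +
      stats::rnorm(n_half + 1L, profile$rom_bias_mm, profile$rom_jitter_sd_mm)
    total <- tau[n_half + 1L]
    t <- seq(0, total, by = 1 / rate_hz)
    if (t[length(t)] < total - 1e-9) t <- c(t, total)
    seg <- pmin(pmax(findInterval(t, tau), 1L), n_half)
    frac <- (t - tau[seg]) / dur[seg]
    y <- v[seg] + (v[seg + 1L] - v[seg]) * (1 - cos(pi * frac)) / 2
    y <- y + stats::rnorm(length(y), 0, profile$noise_sd_mm)
    tr <- motion_trace(t, y, exercise_kind = exercise_kind,
                       nominal_rate_hz = rate_hz)
    attr(tr, "schedule") <- data.frame(
      time_s = tau, y_mm = v,
      phase_label = rep_len(c("eccentric", "concentric"), n_half + 1L))
    tr
  })
}

#' Synthetic breathing pattern
#'
#' @param mode `"paced_per_cycle"` places one exhalation burst per movement
#'   cycle, starting at each concentric (top) endpoint — exhaling on the
#'   lowering phase; `"free"` places bursts at seeded irregular intervals;
#'   `"holding"` behaves like `paced_per_cycle` but silences the envelope
#'   inside `hold_intervals` (a modelled Valsalva: attempted exhalation
#'   against a closed airway produces no microphone signal).
#' @param hold_intervals List of `c(start_s, end_s)` silences; must not
#'   overlap.
#' @param burst_amp Envelope amplitude of an exhalation (0-1).
#' @param burst_dur_s Exhalation burst length, seconds.
#' @param noise_floor Baseline envelope level outside bursts (0-1).
#' @return An object of class `breath_pattern`.
#' @export
breath_pattern <- function(mode = c("paced_per_cycle", "free", "holding"),
                           hold_intervals = list(), burst_amp = 0.8,
                           burst_dur_s = 1, noise_floor = 0.05) {
  mode <- match.arg(mode)
  check_number(burst_amp, "burst_amp", 0, 1, strict_lower = TRUE)
  check_number(burst_dur_s, "burst_dur_s", 0, strict_lower = TRUE)
  check_number(noise_floor, "noise_floor", 0, 1)
  if (length(hold_intervals)) {
    iv <- do.call(rbind, lapply(hold_intervals, function(h) {
      if (length(h) != 2L || h[2] <= h[1]) {
        stop_input("hold intervals must be c(start_s, end_s) with end > start")
      }
      h
    }))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      stop_input("hold intervals must not overlap")
    }
  }
  structure(list(mode = mode, hold_intervals = hold_intervals,
                 burst_amp = burst_amp, burst_dur_s = burst_dur_s,
                 noise_floor = noise_floor),
            class = "breath_pattern")
}

#' Generate a synthetic breath envelope for a motion trace
#'
#' Exhalation bursts are raised-cosine (Hann) humps of `burst_dur_s` at
#' `burst_amp` over a low noise floor. In `paced_per_cycle` (and `holding`)
#' mode one burst starts at each concentric endpoint of the motion; in
#' `free` mode burst onsets walk forward with seeded jittered gaps. Hold
#' intervals silence the envelope completely. Deterministic given `seed`.
#'
#' @param pattern A [breath_pattern()].
#' @param motion The [motion_trace()] the breathing accompanies (uses its
#'   generated endpoint schedule when present, otherwise detects endpoints).
#' @param rate_hz Envelope frame rate, Hz.
#' @param seed Integer seed.
#' @return A [breath_envelope()] spanning the motion trace.
#' @export
gen_breath <- function(pattern, motion, rate_hz = 30, seed = 1) {
  stopifnot(inherits(pattern, "breath_pattern"))
  total <- motion$time_s[nrow(motion)]
  t <- seq(0, total, by = 1 / rate_hz)
  with_seed(seed, {
    onsets <- if (pattern$mode == "free") {
      on <- c()
      cur <- abs(stats::rnorm(1, 2, 1))
      while (cur < total) {
        on <- c(on, cur)
        cur <- cur + pmax(stats::rnorm(1, 4, 1), pattern$burst_dur_s + 0.6)
      }
      on
    } else {
      sched <- attr(motion, "schedule")
      if (is.null(sched)) {
        sm <- smooth_trace(motion)
        sched <- detect_endpoints(sm)
      }
      sched$time_s[sched$phase_label == "concentric"]
    }
    amp <- rep(pattern$noise_floor, length(t))
    for (on in onsets) {
      in_burst <- t >= on & t <= on + pattern$burst_dur_s
      hump <- pattern$burst_amp *
        (1 - cos(2 * pi * (t[in_burst] - on) / pattern$burst_dur_s)) / 2
      amp[in_burst] <- pmax(amp[in_burst], pattern$noise_floor + hump)
    }
    if (pattern$noise_floor > 0) {
      amp <- amp + stats::rnorm(length(t), 0, pattern$noise_floor / 10)
    }
    for (h in pattern$hold_intervals) {
      amp[t >= h[1] & t <= h[2]] <- 0
    }
    breath_envelope(t, clamp(amp, 0, 1))
  })
}

#' Generate a full synthetic session
#'
#' Three exercises (bicep curl, frontal shoulder raise, inclined pectoral
#' fly) of `n_sets` sets each, with per-set motion traces and breath
#' envelopes. Each set uses an independent sub-seed derived
#' deterministically from the master seed and the (exercise, set) indices,
#' so sets are reproducible individually and jointly.
#'
#' @param profile An [exerciser_profile()] shared by all sets.
#' @param pattern A [breath_pattern()] shared by all sets.
#' @param n_sets Sets per exercise (default 3).
#' @param rate_hz Sampling rate, Hz.
#' @param seed Master integer seed.
#' @return A list of per-set bundles, each
#'   `list(exercise_kind, set, motion, breath)`.
#' @export
gen_session <- function(profile = exerciser_profile(),
                        pattern = breath_pattern(), n_sets = 3,
                        rate_hz = 30, seed = 1) {
  check_number(n_sets, "n_sets", 1)
  kinds <- c("bicep_curl", "shoulder_raise", "pectoral_fly")
  out <- list()
  for (ex in seq_along(kinds)) {
    for (s in seq_len(n_sets)) {
      sub <- derive_seed(seed, ex, s)
      motion <- gen_motion(profile, rate_hz, seed = sub,
                           exercise_kind = kinds[ex])
      breath <- gen_breath(pattern, motion, rate_hz,
                           seed = derive_seed(sub, 999L))
      out[[length(out) + 1L]] <- list(exercise_kind = kinds[ex], set = s,
                                      motion = motion, breath = breath)
    }
  }
  out
}
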