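#' Session configuration
#'
#' Bundles every tunable of the feedback engine for one session. In the
#' `"control"` condition all feedback outputs (earcons, pitch signal, light
#' channel) are disabled but exercise metrics are still computed, mirroring
#' a no-feedback exercise set; `"ambient_sonification"` enables the full
#' feedback chain.
#'
#' @param condition `"control"` or `"ambient_sonification"`.
#' @param n_sets Sets per exercise (used by session-level generators).
#' @param n_reps_per_set Repetitions per set; the set-complete earcon fires
#'   when this many repetitions have been completed (default 10).
#' @param pitch_params A [pitch_map_params()].
#' @param smoothing A [smoothing_params()].
#' @param detector A [breath_detector_params()].
#' @param calibration A [calibration_profile()]; defaults to the synthetic
#'   generator's geometry (bottom 100 mm, top 500 mm).
#' @param period_s Ideal repetition period, seconds (default 6 = 3 s
#'   concentric + 3 s eccentric).
#' @param min_half_period_s,min_prominence_mm Endpoint-detector settings.
#' @param valsalva_timeout_s Silence duration triggering lights-off.
#' @param pacer_up_s,pacer_down_s Light pacer ramp durations.
#' @param seed Integer seed for any stochastic companion generation.
#' @return An object of class `session_config`.
#' @export
session_config <- function(condition = c("ambient_sonification", "control"),
                           n_sets = 3, n_reps_per_set = 10,
                           pitch_params = pitch_map_params(),
                           smoothing = smoothing_params(),
                           detector = breath_detector_params(),
                           calibration = calibration_profile(100, 500),
                           period_s = 6, min_half_period_s = 0.5,
                           min_prominence_mm = 20, valsalva_timeout_s = 6,
                           pacer_up_s = 3, pacer_down_s = 3, seed = 1) {
  condition <- match.arg(condition)
  check_number(n_sets, "n_sets", 1)
  check_number(n_reps_per_set, "n_reps_per_set", 1)
  check_number(period_s, "period_s", 0, strict_lower = TRUE)
  structure(list(condition = condition, n_sets = as.integer(n_sets),
                 n_reps_per_set = as.integer(n_reps_per_set),
                 pitch_params = pitch_params, smoothing = smoothing,
                 detector = detector, calibration = calibration,
                 period_s = period_s, min_half_period_s = min_half_period_s,
                 min_prominence_mm = min_prominence_mm,
                 valsalva_timeout_s = valsalva_timeout_s,
                 pacer_up_s = pacer_up_s, pacer_down_s = pacer_down_s,
                 seed = seed),
            class = "session_config")
}

#' Run the feedback engine over one recorded set
#'
#' Offline re-enactment of the closed feedback loop, processed strictly in
#' time order: the raw position signal is smoothed causally, turning points
#' are detected, the sinusoidal reference model is re-anchored at each
#' detected endpoint, the measured-vs-ideal velocity difference drives the
#' pitch-transposition signal, endpoint classifications drive the earcons,
#' and the breath envelope drives the exhalation count, light pacer and
#' breath-hold monitor. Every emitted value at time t depends only on
#' inputs up to one sample beyond t (the single frame of lookahead in the
#' central-difference velocity).
#'
#' @param motion A [motion_trace()] (raw; smoothing happens inside).
#' @param breath A [breath_envelope()] on the same clock, or `NULL` for a
#'   motion-only run.
#' @param config A [session_config()].
#' @return An object of class `session_result`: a list with `events`
#'   (feedback event log), `pitch` (`time_s`, `transpose_octaves`,
#'   `output_freq_hz`), `light` (`time_s`, `brightness`, `on`), `metrics`
#'   (one-row [set_metrics()]), `reps`, `endpoints`, `trace` (smoothed) and
#'   `exhalations`.
#' @export
run_session <- function(motion, breath = NULL, config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  if (is.null(motion) || nrow(motion) < 3L) {
    stop_input("motion input is empty or too short")
  }
  if (!is.null(breath)) {
    if (nrow(breath) == 0L) stop_input("breath input is empty")
    if (min(breath$time_s) > motion$time_s[1] + 1 ||
        breath$time_s[1] < motion$time_s[1] - 1) {
      stop_input("motion and breath inputs are misaligned")
    }
  }
  feedback_on <- config$condition == "ambient_sonification"
  t0 <- motion$time_s[1]
  t_end <- motion$time_s[nrow(motion)]

  sm <- smooth_trace(motion, config$smoothing)
  eps <- detect_endpoints(sm, config$min_half_period_s,
                          config$min_prominence_mm)
  eps <- refine_endpoints(eps, motion)
  eps_a <- anchor_set_endpoints(eps, motion)
  prepended <- nrow(eps_a) > nrow(eps) &&
    (nrow(eps) == 0L || eps_a$time_s[1] < eps$time_s[1])

  model <- reference_model(config$calibration, config$period_s,
                           phase_anchor_s = t0)
  # walk the endpoints: timing error against the model aligned at the
  # previous endpoint, then realign. Keep the per-interval anchors so the
  # per-sample reference velocity uses only endpoints already observed.
  anchors <- numeric(nrow(eps_a) + 1L)
  anchors[1] <- model$phase_anchor_s
  if (nrow(eps_a)) {
    for (i in seq_len(nrow(eps_a))) {
      ep <- eps_a[i, ]
      eps_a$timing_error_s[i] <- endpoint_timing_error(model, ep)
      model <- realign_phase(model, ep)
      anchors[i + 1L] <- model$phase_anchor_s
    }
    eps_a$rom_class <- classify_endpoint(eps_a$y_mm, config$calibration,
                                         eps_a$phase_label)
  }
  reps <- segment_reps(eps_a)

  # breath chain
  exh <- data.frame(onset_s = numeric(), offset_s = numeric())
  n_exh <- 0L
  if (!is.null(breath)) {
    exh <- detect_exhalations(breath, config$detector)
    n_exh <- count_exhalations(exh, t0, t_end)
  }

  events <- new_events()
  pitch <- NULL
  light <- NULL
  if (feedback_on) {
    ear_eps <- if (prepended) eps_a[-1, , drop = FALSE] else eps_a
    class(ear_eps) <- c("endpoint_events", "data.frame")
    events <- emit_earcons(ear_eps, set_size = config$n_reps_per_set)

    vel <- estimate_velocity(sm)
    seg <- findInterval(vel$time_s, eps_a$time_s) + 1L  # anchor interval
    v_ref <- numeric(nrow(vel))
    for (k in unique(seg)) {
      idx <- seg == k
      mk <- model
      mk$phase_anchor_s <- anchors[k]
      v_ref[idx] <- reference_velocity(mk, vel$time_s[idx])
    }
    pp <- config$pitch_params
    pp$dv_sat_mm_per_s <- resolve_dv_sat(pp, model)
    tr_oct <- pitch_transpose(vel$v_mm_per_s, v_ref, pp)
    carrier <- sqrt(pp$base_low_hz * pp$base_high_hz)
    pitch <- data.frame(time_s = vel$time_s, transpose_octaves = tr_oct,
                        output_freq_hz = transposed_frequency(carrier, tr_oct))

    if (!is.null(breath)) {
      lev <- valsalva_monitor(exh, horizon_s = max(t_end, t0 + 1),
                              timeout_s = config$valsalva_timeout_s)
      events <- rbind(events, lev)
      light <- light_signal(sm$time_s, lev, config$pacer_up_s,
                            config$pacer_down_s)
    } else {
      light <- light_signal(sm$time_s, new_events(), config$pacer_up_s,
                            config$pacer_down_s)
    }
    events <- events[order(events$time_s), , drop = FALSE]
    rownames(events) <- NULL
    class(events) <- c("feedback_events", "data.frame")
  }

  structure(list(events = events, pitch = pitch, light = light,
                 metrics = set_metrics(reps, n_exh), reps = reps,
                 endpoints = eps_a, trace = sm, exhalations = exh),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<session_result> %d reps, con %.2f (SD %.2f) s, ",
                     "ecc %.2f (SD %.2f) s, %d exhalations, %d events\n"),
              m$n_reps, m$mean_con_s, m$sd_con_s, m$mean_ecc_s, m$sd_ecc_s,
              m$exhalation_count, nrow(x$events)))
  invisible(x)
}

#' Summarise a collection of per-set runs
#'
#' Builds the per-set metrics table and condition-level aggregates.
#' Contraction times are aggregated at the repetition level (pooled over
#' all repetitions of a condition), endpoint variation and respiration at
#' the set level, matching how these measures are defined.
#'
#' @param runs A list of entries, each a list with `exercise_kind`, `set`,
#'   `condition` and `result` (a [run_session()] output).
#' @return A list with `per_set` (one row per set: labels, [set_metrics()]
#'   columns and event counts) and `by_condition` (one row per condition:
#'   pooled repetition-level contraction-time mean/SD, set-level means of
#'   endpoint variation and exhalation count).
#' @export
summarize_sets <- function(runs) {
  if (length(runs) == 0L) stop_input("no runs to summarise")
  per_set <- do.call(rbind, lapply(runs, function(r) {
    m <- r$result$metrics
    ev <- r$result$events
    cbind(data.frame(exercise = r$exercise_kind, set = r$set,
                     condition = r$condition),
          as.data.frame(m),
          data.frame(
            n_success_earcons = sum(grepl("^earcon_success", ev$kind)),
            n_corrective_earcons = sum(grepl("^earcon_corrective", ev$kind)),
            n_set_complete = sum(ev$kind == "earcon_set_complete"),
            n_lights_off = sum(ev$kind == "lights_off")))
  }))
  rownames(per_set) <- NULL
  by_condition <- do.call(rbind, lapply(split(runs, vapply(
    runs, function(r) r$condition, "")), function(grp) {
      con <- unlist(lapply(grp, function(r) r$result$reps$concentric_time_s))
      ecc <- unlist(lapply(grp, function(r) r$result$reps$eccentric_time_s))
      ms <- do.call(rbind, lapply(grp, function(r) r$result$metrics))
      data.frame(condition = grp[[1]]$condition,
                 n_sets = length(grp), n_reps = length(con),
                 mean_con_s = mean(con),
                 sd_con_s = if (length(con) > 1) stats::sd(con) else 0,
                 mean_ecc_s = mean(ecc),
                 sd_ecc_s = if (length(ecc) > 1) stats::sd(ecc) else 0,
                 mean_con_endpoint_var_mm = mean(ms$sd_con_endpoint_mm),
                 mean_ecc_endpoint_var_mm = mean(ms$sd_ecc_endpoint_mm),
                 mean_exhalations = mean(ms$exhalation_count))
    }))
  rownames(by_condition) <- NULL
  list(per_set = per_set, by_condition = by_condition)
}
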