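#' Pitch-mapping parameters
#'
#' The sonification loops a melody spanning `base_low_hz`-`base_high_hz`
#' (defaults 185-247 Hz) and transposes it by up to one octave either way in
#' proportion to the difference between measured and ideal movement
#' velocity, so the emitted frequency always stays within
#' `[base_low_hz/2, base_high_hz*2]` (92.5-494 Hz at the defaults). The
#' transposition saturates at a velocity difference of `dv_sat_mm_per_s`;
#' by default this equals the reference model's peak velocity
#' `2*pi*amplitude/period`, so a complete stop or a doubled pace at
#' mid-phase reaches the clamp.
#'
#' @param base_low_hz Lowest melody note, Hz.
#' @param base_high_hz Highest melody note, Hz; must exceed `base_low_hz`.
#' @param dv_sat_mm_per_s Velocity-difference magnitude (mm/s) at which the
#'   transposition saturates at one octave.
#' @param direction `"faster_is_higher"` (default) raises pitch when the
#'   exerciser moves faster than the reference; `"faster_is_lower"` flips
#'   the polarity.
#' @return An object of class `pitch_map_params`.
#' @export
pitch_map_params <- function(base_low_hz = 185, base_high_hz = 247,
                             dv_sat_mm_per_s = NULL,
                             direction = c("faster_is_higher",
                                           "faster_is_lower")) {
  direction <- match.arg(direction)
  check_number(base_low_hz, "base_low_hz", 0, strict_lower = TRUE)
  check_number(base_high_hz, "base_high_hz", base_low_hz,
               strict_lower = TRUE)
  if (!is.null(dv_sat_mm_per_s)) {
    check_number(dv_sat_mm_per_s, "dv_sat_mm_per_s", 0, strict_lower = TRUE)
  }
  structure(list(base_low_hz = base_low_hz, base_high_hz = base_high_hz,
                 dv_sat_mm_per_s = dv_sat_mm_per_s, direction = direction),
            class = "pitch_map_params")
}

# dv_sat defaulting needs the reference model's peak velocity.
resolve_dv_sat <- function(params, model) {
  if (!is.null(params$dv_sat_mm_per_s)) return(params$dv_sat_mm_per_s)
  2 * pi * model$calibration$amplitude_mm / model$period_s
}

#' Map a velocity error to a transposition, in octaves
#'
#' Linear map of the measured-minus-ideal velocity difference onto the
#' transpose dial, clamped to one octave either way:
#' `clamp((v_meas - v_ref) / dv_sat, -1, +1)` (sign flipped for
#' `direction = "faster_is_lower"`).
#'
#' @param v_meas Measured velocity, mm/s (vectorised).
#' @param v_ref Ideal (reference-model) velocity, mm/s.
#' @param params A [pitch_map_params()]; `dv_sat_mm_per_s` must be set
#'   (resolve it against a reference model first, or pass it explicitly).
#' @return Transposition in octaves, in `[-1, 1]`.
#' @export
pitch_transpose <- function(v_meas, v_ref, params = pitch_map_params()) {
  dv_sat <- params$dv_sat_mm_per_s
  if (is.null(dv_sat)) {
    stop_input("dv_sat_mm_per_s is unset; supply it or resolve against a ",
               "reference model")
  }
  x <- clamp((v_meas - v_ref) / dv_sat, -1, 1)
  if (params$direction == "faster_is_lower") -x else x
}

#' Apply an octave transposition to a base frequency
#'
#' @param base_freq_hz Frequency of the currently sounding melody note, Hz.
#' @param transpose_octaves Transposition in octaves, must lie in `[-1, 1]`.
#' @return `base_freq_hz * 2^transpose_octaves`, Hz.
#' @export
transposed_frequency <- function(base_freq_hz, transpose_octaves) {
  if (any(!is.finite(transpose_octaves)) ||
      any(transpose_octaves < -1) || any(transpose_octaves > 1)) {
    stop_input("transpose_octaves must lie in [-1, 1]")
  }
  base_freq_hz * 2^transpose_octaves
}

# Nominal earcon pitches (payload only; no audio rendering is mandated).
# Concentric earcons are pitched above their eccentric counterparts.
EARCON_PITCH_HZ <- c(earcon_success_con = 660, earcon_success_ecc = 440,
                     earcon_corrective_con = 622, earcon_corrective_ecc = 415,
                     earcon_set_complete = 880)

#' Classify a reached endpoint against the calibrated range of motion
#'
#' An endpoint within `tolerance_mm` of its calibrated target is a
#' `success`; past the target by more than the tolerance in the movement
#' direction (above the top target for concentric, below the bottom target
#' for eccentric) is an `overshoot` ("went too far", triggering a corrective
#' earcon); short of the target is an `undershoot`, for which the system
#' stays silent.
#'
#' @param y_mm Endpoint position(s), mm (vectorised).
#' @param cal A [calibration_profile()].
#' @param phase_label `"concentric"` or `"eccentric"` (recycled).
#' @return Character vector: `"success"`, `"overshoot"` or `"undershoot"`.
#' @export
classify_endpoint <- function(y_mm, cal, phase_label) {
  stopifnot(inherits(cal, "calibration_profile"))
  target <- ifelse(phase_label == "concentric", cal$y_con_mm, cal$y_ecc_mm)
  past <- ifelse(phase_label == "concentric", y_mm - target, target - y_mm)
  ifelse(abs(y_mm - target) <= cal$tolerance_mm, "success",
         ifelse(past > cal$tolerance_mm, "overshoot", "undershoot"))
}

new_events <- function(time_s = numeric(), kind = character(),
                       pitch_hz = rep(NA_real_, length(time_s)),
                       timing_error_s = rep(NA_real_, length(time_s)),
                       rom_class = rep(NA_character_, length(time_s))) {
  structure(data.frame(time_s = time_s, kind = kind, pitch_hz = pitch_hz,
                       timing_error_s = timing_error_s, rom_class = rom_class,
                       stringsAsFactors = FALSE),
            class = c("feedback_events", "data.frame"))
}

#' Emit earcon events for a classified endpoint stream
#'
#' Success and overshoot endpoints yield a success or corrective earcon at
#' the endpoint time (concentric variants carry a higher nominal pitch than
#' eccentric ones); undershoot endpoints yield no sound. A repetition
#' completes at each eccentric endpoint; when the completed-repetition count
#' reaches `set_size`, a single set-complete earcon is emitted at that
#' endpoint's time.
#'
#' @param endpoints A time-ordered `endpoint_events` data.frame whose
#'   `rom_class` is filled in (see [classify_endpoint()]). Pass the stream
#'   *excluding* the set-start anchor: the resting start position is not a
#'   reached endpoint.
#' @param set_size Repetitions per set (default 10).
#' @return A `feedback_events` data.frame: `time_s`, `kind`, `pitch_hz`,
#'   `timing_error_s`, `rom_class`.
#' @export
emit_earcons <- function(endpoints, set_size = 10) {
  check_alternating(endpoints)
  out <- new_events()
  reps_done <- 0L
  set_done <- FALSE
  for (i in seq_len(nrow(endpoints))) {
    ep <- endpoints[i, ]
    if (is.na(ep$rom_class)) stop_input("endpoints must be classified")
    if (ep$rom_class != "undershoot") {
      stemn <- if (ep$rom_class == "success") "earcon_success_" else "earcon_corrective_"
      kind <- paste0(stemn, if (ep$phase_label == "concentric") "con" else "ecc")
      out <- rbind(out, new_events(ep$time_s, kind,
                                   unname(EARCON_PITCH_HZ[kind]),
                                   ep$timing_error_s, ep$rom_class))
    }
    if (ep$phase_label == "eccentric") {
      reps_done <- reps_done + 1L
      if (!set_done && reps_done >= set_size) {
        out <- rbind(out, new_events(ep$time_s, "earcon_set_complete",
                                     unname(EARCON_PITCH_HZ["earcon_set_complete"])))
        set_done <- TRUE
      }
    }
  }
  class(out) <- c("feedback_events", "data.frame")
  out
}
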