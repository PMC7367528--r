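#' Range-of-motion calibration profile
#'
#' Per-user calibration of the target range of motion: the eccentric
#' (bottom) and concentric (top) endpoint positions, and the half-width of
#' the success band around each endpoint used to classify reached endpoints.
#'
#' @param y_ecc_mm Target eccentric (bottom) endpoint position, mm.
#' @param y_con_mm Target concentric (top) endpoint position, mm; must
#'   exceed `y_ecc_mm`.
#' @param tolerance_mm Half-width of the success band at each endpoint, mm.
#' @return An object of class `calibration_profile` with derived fields
#'   `midpoint_mm` and `amplitude_mm`.
#' @export
calibration_profile <- function(y_ecc_mm, y_con_mm, tolerance_mm = 20) {
  check_number(y_ecc_mm, "y_ecc_mm")
  check_number(y_con_mm, "y_con_mm")
  check_number(tolerance_mm, "tolerance_mm", 0)
  if (y_con_mm <= y_ecc_mm) stop_input("y_con_mm must exceed y_ecc_mm")
  structure(list(y_ecc_mm = y_ecc_mm, y_con_mm = y_con_mm,
                 midpoint_mm = (y_con_mm + y_ecc_mm) / 2,
                 amplitude_mm = (y_con_mm - y_ecc_mm) / 2,
                 tolerance_mm = tolerance_mm),
            class = "calibration_profile")
}

#' Phase-anchored sinusoidal reference movement model
#'
#' The ideal repetition is a sinusoid through the calibrated range of
#' motion whose period equals the instructed pace: 3 s concentric (lifting)
#' plus 3 s eccentric (lowering) = 6 s by default. `phase_anchor_s` is a
#' time at which the model sits at the eccentric endpoint about to lift;
#' the anchor is updated to follow the exerciser via [realign_phase()].
#'
#' @param calibration A [calibration_profile()].
#' @param period_s Full repetition period in seconds (default 6).
#' @param phase_anchor_s Time (s) at which the model is at the eccentric
#'   endpoint moving upward.
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(calibration, period_s = 6, phase_anchor_s = 0) {
  stopifnot(inherits(calibration, "calibration_profile"))
  check_number(period_s, "period_s", 0, strict_lower = TRUE)
  check_number(phase_anchor_s, "phase_anchor_s")
  structure(list(period_s = period_s, phase_anchor_s = phase_anchor_s,
                 calibration = calibration),
            class = "reference_model")
}

#' Ideal position of the reference model
#'
#' `midpoint - amplitude * cos(2*pi*(t - anchor)/period)`: the model is at
#' the eccentric endpoint at the phase anchor and at the concentric endpoint
#' half a period later.
#'
#' @param model A [reference_model()].
#' @param t Time(s) in seconds (vectorised).
#' @return Ideal position(s) in mm.
#' @export
reference_position <- function(model, t) {
  cal <- model$calibration
  cal$midpoint_mm -
    cal$amplitude_mm * cos(2 * pi * (t - model$phase_anchor_s) / model$period_s)
}

#' Ideal velocity of the reference model
#'
#' Time derivative of [reference_position()]; its peak magnitude is
#' `2*pi*amplitude/period` (about 209 mm/s for a 200 mm amplitude at the
#' default 6 s period), reached mid-phase.
#'
#' @inheritParams reference_position
#' @return Ideal velocity(ies) in mm/s.
#' @export
reference_velocity <- function(model, t) {
  cal <- model$calibration
  (2 * pi * cal$amplitude_mm / model$period_s) *
    sin(2 * pi * (t - model$phase_anchor_s) / model$period_s)
}

#' Re-anchor the reference model at a detected endpoint
#'
#' Sets the phase anchor so the model reaches the endpoint's phase exactly
#' at the endpoint's time: an eccentric endpoint anchors directly, a
#' concentric endpoint anchors half a period earlier. All other fields are
#' unchanged; realigning twice on the same endpoint is idempotent.
#'
#' @param model A [reference_model()].
#' @param endpoint A one-row slice of an `endpoint_events` data.frame (or
#'   any list with `time_s` and `phase_label`).
#' @return The realigned `reference_model`.
#' @export
realign_phase <- function(model, endpoint) {
  anchor <- if (endpoint$phase_label == "eccentric") {
    endpoint$time_s
  } else {
    endpoint$time_s - model$period_s / 2
  }
  model$phase_anchor_s <- anchor
  model
}

#' Timing error of an observed endpoint against the reference
#'
#' Difference between the observed endpoint time and the nearest ideal time
#' at which the model reaches the same endpoint type. With the model
#' anchored at the previous endpoint, this is the deviation of the just-
#' completed half-cycle from the ideal half-period: positive = late (too
#' slow), negative = early (too fast).
#'
#' @inheritParams realign_phase
#' @return Timing error in seconds.
#' @export
endpoint_timing_error <- function(model, endpoint) {
  offset <- if (endpoint$phase_label == "eccentric") 0 else model$period_s / 2
  # ideal times: phase_anchor + offset + k * period, k integer
  rel <- (endpoint$time_s - model$phase_anchor_s - offset) / model$period_s
  (rel - round(rel)) * model$period_s
}
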