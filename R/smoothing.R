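#' Smoothing parameters for the Kinect-style joint filter
#'
#' Parameters of the causal double-exponential (Holt) smoother applied to
#' raw hand-position samples before any feature extraction. The defaults
#' reproduce the capture pipeline's filter configuration
#' (smoothing 0.5, correction 0.8, prediction 0.3 frames, jitter radius and
#' max deviation radius 0.01 m = 10 mm; positions here are in mm).
#'
#' @param smoothing Level-smoothing weight in `[0, 1]`; 0 disables Holt
#'   smoothing (the jitter and deviation clamps still apply).
#' @param correction Trend-correction weight in `[0, 1]`.
#' @param prediction Forward-extrapolation horizon in frames (>= 0).
#' @param jitter_radius_mm Deviations of the raw sample from the previous
#'   filtered value at or below this radius are attenuated proportionally
#'   toward the previous filtered value; larger deviations pass through.
#' @param max_deviation_radius_mm The filtered output is clamped so it never
#'   departs from the raw sample by more than this radius.
#'
#' @return An object of class `smoothing_params` (a named list).
#' @export
smoothing_params <- function(smoothing = 0.5, correction = 0.8,
                             prediction = 0.3,
                             jitter_radius_mm = 10,
                             max_deviation_radius_mm = 10) {
  check_number(smoothing, "smoothing", 0, 1)
  check_number(correction, "correction", 0, 1)
  check_number(prediction, "prediction", 0)
  check_number(jitter_radius_mm, "jitter_radius_mm", 0, strict_lower = TRUE)
  check_number(max_deviation_radius_mm, "max_deviation_radius_mm", 0,
               strict_lower = TRUE)
  structure(list(smoothing = smoothing, correction = correction,
                 prediction = prediction,
                 jitter_radius_mm = jitter_radius_mm,
                 max_deviation_radius_mm = max_deviation_radius_mm),
            class = "smoothing_params")
}

#' Smooth a raw motion trace
#'
#' Causal double-exponential (Holt) smoothing with jitter attenuation and a
#' maximum-deviation clamp, the standard Kinect skeletal-joint filter
#' recurrence. For each raw sample x_i:
#'
#' 1. jitter filter: if `|x_i - f_{i-1}| <= jitter_radius`, the sample is
#'    pulled toward the previous filtered value `f_{i-1}` in proportion to
#'    the deviation; otherwise it passes unchanged;
#' 2. Holt recurrence: `f_i = (1-s)*x'_i + s*(f_{i-1} + b_{i-1})`,
#'    `b_i = c*(f_i - f_{i-1}) + (1-c)*b_{i-1}` with level weight `s` and
#'    trend weight `c` (first sample initialises `f_1 = x'_1`, `b_1 = 0`;
#'    the second uses the two-sample mean);
#' 3. prediction: the output is `f_i + prediction * b_i`;
#' 4. deviation clamp: the output is pulled back toward the raw sample so it
#'    never departs from it by more than `max_deviation_radius_mm`.
#'
#' The filter is causal: output `i` depends only on inputs `1..i`.
#'
#' @param raw A [motion_trace()] with at least 2 samples.
#' @param params A [smoothing_params()] object.
#' @return A `motion_trace` with identical timestamps and smoothed `y_mm`.
#' @export
smooth_trace <- function(raw, params = smoothing_params()) {
  stopifnot(inherits(params, "smoothing_params"))
  if (!inherits(raw, "motion_trace")) {
    raw <- motion_trace(raw$time_s, raw$y_mm)
  }
  n <- nrow(raw)
  if (n < 2L) stop_input("smooth_trace needs at least 2 samples")
  x <- raw$y_mm
  s <- params$smoothing
  cc <- params$correction
  p <- params$prediction
  jr <- params$jitter_radius_mm
  mdr <- params$max_deviation_radius_mm

  out <- numeric(n)
  f_prev <- x[1]
  b_prev <- 0
  raw_prev <- x[1]
  out[1] <- x[1]
  for (i in 2:n) {
    dev <- abs(x[i] - f_prev)
    xf <- if (dev <= jr && jr > 0) {
      x[i] * (dev / jr) + f_prev * (1 - dev / jr)
    } else {
      x[i]
    }
    if (i == 2L) {
      f <- (xf + raw_prev) / 2
      b <- cc * (f - f_prev) + (1 - cc) * b_prev
    } else {
      f <- (1 - s) * xf + s * (f_prev + b_prev)
      b <- cc * (f - f_prev) + (1 - cc) * b_prev
    }
    pred <- f + p * b
    dev_out <- abs(pred - x[i])
    if (dev_out > mdr) {
      pred <- pred * (mdr / dev_out) + x[i] * (1 - mdr / dev_out)
    }
    out[i] <- pred
    f_prev <- f
    b_prev <- b
    raw_prev <- x[i]
  }
  replace_y(raw, out)
}
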