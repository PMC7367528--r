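#' Construct a motion trace
#'
#' A motion trace is the 1-D kinematic record of one exercise set: the
#' vertical position of the tracked hand, in millimetres relative to a body
#' origin (up = positive), sampled at a nominal 30 Hz. For bicep curls and
#' frontal shoulder raises the origin is the exerciser's centre of mass; for
#' inclined pectoral flies the head is the only stable reference and is used
#' instead.
#'
#' @param time_s Numeric vector of sample times in seconds since set start;
#'   must be non-negative and strictly increasing.
#' @param y_mm Numeric vector of vertical hand positions in mm, same length
#'   as `time_s`; must be finite.
#' @param exercise_kind One of `"bicep_curl"`, `"shoulder_raise"`,
#'   `"pectoral_fly"`.
#' @param origin_ref One of `"center_of_mass"`, `"head"`. The head origin is
#'   required for (and only for) the pectoral fly.
#' @param nominal_rate_hz Nominal capture rate in samples per second.
#'
#' @return An object of class `motion_trace`: a data.frame with columns
#'   `time_s` and `y_mm` and attributes `exercise_kind`, `origin_ref`,
#'   `nominal_rate_hz`.
#' @examples
#' tr <- motion_trace(seq(0, 1, by = 0.1), sin(seq(0, 1, by = 0.1)) * 100)
#' @export
motion_trace <- function(time_s, y_mm,
                         exercise_kind = c("bicep_curl", "shoulder_raise",
                                           "pectoral_fly"),
                         origin_ref = NULL,
                         nominal_rate_hz = 30) {
  exercise_kind <- match.arg(exercise_kind)
  if (is.null(origin_ref)) {
    origin_ref <- if (exercise_kind == "pectoral_fly") "head" else "center_of_mass"
  }
  origin_ref <- match.arg(origin_ref, c("center_of_mass", "head"))
  if ((origin_ref == "head") != (exercise_kind == "pectoral_fly")) {
    stop_input("origin_ref must be 'head' for pectoral_fly and ",
               "'center_of_mass' otherwise")
  }
  check_number(nominal_rate_hz, "nominal_rate_hz", 0, strict_lower = TRUE)
  if (length(time_s) != length(y_mm)) {
    stop_input("time_s and y_mm must have equal length")
  }
  if (length(time_s) && (any(!is.finite(time_s)) || any(time_s < 0))) {
    stop_input("time_s must be finite and non-negative")
  }
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    stop_input("sample times must be strictly increasing")
  }
  if (length(y_mm) && any(!is.finite(y_mm))) {
    stop_input("y_mm must be finite")
  }
  structure(
    data.frame(time_s = as.numeric(time_s), y_mm = as.numeric(y_mm)),
    exercise_kind = exercise_kind,
    origin_ref = origin_ref,
    nominal_rate_hz = nominal_rate_hz,
    class = c("motion_trace", "data.frame")
  )
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %s (origin: %s), %d samples @ %g Hz nominal",
              attr(x, "exercise_kind"), attr(x, "origin_ref"),
              nrow(x), attr(x, "nominal_rate_hz")))
  if (nrow(x)) {
    cat(sprintf(", %.2f-%.2f s, y in [%.1f, %.1f] mm",
                x$time_s[1], x$time_s[nrow(x)], min(x$y_mm), max(x$y_mm)))
  }
  cat("\n")
  invisible(x)
}

# Rebuild a motion_trace with new y values, keeping metadata.
replace_y <- function(trace, y_mm) {
  motion_trace(trace$time_s, y_mm,
               exercise_kind = attr(trace, "exercise_kind"),
               origin_ref = attr(trace, "origin_ref"),
               nominal_rate_hz = attr(trace, "nominal_rate_hz"))
}
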