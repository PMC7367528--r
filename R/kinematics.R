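#' Estimate vertical velocity from a motion trace
#'
#' Finite-difference velocity of the hand position: central differences at
#' interior samples, one-sided differences at the two boundaries. Durations
#' come from the timestamps, so irregular frame intervals are handled.
#'
#' @param trace A [motion_trace()] with at least 3 samples (normally the
#'   smoothed trace).
#' @return A data.frame with columns `time_s` and `v_mm_per_s`, one row per
#'   input sample.
#' @export
estimate_velocity <- function(trace) {
  n <- nrow(trace)
  if (n < 3L) stop_input("estimate_velocity needs at least 3 samples")
  t <- trace$time_s
  y <- trace$y_mm
  v <- numeric(n)
  v[1] <- (y[2] - y[1]) / (t[2] - t[1])
  v[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  idx <- 2:(n - 1)
  v[idx] <- (y[idx + 1] - y[idx - 1]) / (t[idx + 1] - t[idx - 1])
  data.frame(time_s = t, v_mm_per_s = v)
}

new_endpoints <- function(time_s = numeric(), y_mm = numeric(),
                          phase_label = character(),
                          timing_error_s = rep(NA_real_, length(time_s)),
                          rom_class = rep(NA_character_, length(time_s))) {
  structure(data.frame(time_s = time_s, y_mm = y_mm,
                       phase_label = phase_label,
                       timing_error_s = timing_error_s,
                       rom_class = rom_class,
                       stringsAsFactors = FALSE),
            class = c("endpoint_events", "data.frame"))
}

#' Detect concentric and eccentric endpoints (turning points)
#'
#' Scans a smoothed position signal for turning points between the lifting
#' and lowering phases: alternating local maxima (concentric endpoints, top
#' of the lift) and local minima (eccentric endpoints, bottom). A turning
#' point is confirmed only when the signal reverses away from it by at least
#' `min_prominence_mm`, which makes the detector robust to residual jitter;
#' a candidate closer than `min_half_period_s` to the previously confirmed
#' endpoint is absorbed rather than emitted, so emitted endpoints always
#' alternate in phase. Ties between equal adjacent samples resolve to the
#' earliest sample. Only interior turning points — confirmed by a reversal
#' on both sides — are returned; see [anchor_set_endpoints()] for the
#' set-boundary convention.
#'
#' @param trace A smoothed [motion_trace()].
#' @param min_half_period_s Minimum time between consecutive endpoints, in
#'   seconds.
#' @param min_prominence_mm Minimum excursion (mm) between consecutive
#'   endpoints.
#' @return An `endpoint_events` data.frame with columns `time_s`, `y_mm`,
#'   `phase_label` (`"concentric"` for maxima, `"eccentric"` for minima),
#'   and placeholder `timing_error_s` / `rom_class` columns (`NA` until
#'   reference alignment and classification).
#' @export
detect_endpoints <- function(trace, min_half_period_s = 0.5,
                             min_prominence_mm = 20) {
  check_number(min_half_period_s, "min_half_period_s", 0, strict_lower = TRUE)
  check_number(min_prominence_mm, "min_prominence_mm", 0, strict_lower = TRUE)
  t <- trace$time_s
  y <- trace$y_mm
  n <- length(y)
  ev_t <- numeric()
  ev_y <- numeric()
  ev_lab <- character()
  if (n >= 2L) {
    dir <- 0L           # 0 unknown, +1 rising (tracking a max), -1 falling
    cand <- 1L          # index of current candidate extremum
    pivot_min <- 1L     # running extrema while direction unknown
    pivot_max <- 1L
    last_time <- -Inf
    for (i in 2:n) {
      if (dir == 0L) {
        if (y[i] < y[pivot_min]) pivot_min <- i
        if (y[i] > y[pivot_max]) pivot_max <- i
        if (y[i] - y[pivot_min] >= min_prominence_mm) {
          dir <- 1L
          w <- pivot_min:i
          cand <- w[which.max(y[w])]
        } else if (y[pivot_max] - y[i] >= min_prominence_mm) {
          dir <- -1L
          w <- pivot_max:i
          cand <- w[which.min(y[w])]
        }
      } else if (dir == 1L) {
        if (y[i] > y[cand]) cand <- i
        if (y[cand] - y[i] >= min_prominence_mm) {
          if (t[cand] - last_time >= min_half_period_s) {
            ev_t <- c(ev_t, t[cand]); ev_y <- c(ev_y, y[cand])
            ev_lab <- c(ev_lab, "concentric")
            last_time <- t[cand]
            dir <- -1L
            w <- cand:i
            cand <- w[which.min(y[w])]
          }
          # else: reversal too soon after the previous endpoint -> jitter;
          # keep extending the current candidate.
        }
      } else {
        if (y[i] < y[cand]) cand <- i
        if (y[i] - y[cand] >= min_prominence_mm) {
          if (t[cand] - last_time >= min_half_period_s) {
            ev_t <- c(ev_t, t[cand]); ev_y <- c(ev_y, y[cand])
            ev_lab <- c(ev_lab, "eccentric")
            last_time <- t[cand]
            dir <- 1L
            w <- cand:i
            cand <- w[which.max(y[w])]
          }
        }
      }
    }
  }
  new_endpoints(ev_t, ev_y, ev_lab)
}

#' Refine endpoint coordinates against the raw signal
#'
#' The causal smoother delays its output, so turning points detected on the
#' smoothed signal lag the true movement reversal by the filter's group
#' delay. Each detected endpoint is re-localised to the raw signal's
#' extremum within `window_s` of the smoothed detection — detection stays
#' robust (it sees only the smoothed signal) while the reported time and
#' position come from the measurement itself. A refinement that would break
#' the strict time ordering of the endpoint sequence is discarded for that
#' endpoint.
#'
#' @param endpoints Output of [detect_endpoints()].
#' @param raw The unsmoothed [motion_trace()].
#' @param window_s Half-width of the search window, seconds.
#' @return The refined `endpoint_events` data.frame.
#' @export
refine_endpoints <- function(endpoints, raw, window_s = 0.25) {
  if (nrow(endpoints) == 0L) return(endpoints)
  t <- raw$time_s
  y <- raw$y_mm
  new_t <- endpoints$time_s
  new_y <- endpoints$y_mm
  for (i in seq_len(nrow(endpoints))) {
    idx <- which(t >= endpoints$time_s[i] - window_s &
                   t <= endpoints$time_s[i] + window_s)
    if (length(idx) == 0L) next
    j <- if (endpoints$phase_label[i] == "concentric") {
      idx[which.max(y[idx])]
    } else {
      idx[which.min(y[idx])]
    }
    new_t[i] <- t[j]
    new_y[i] <- y[j]
  }
  ok <- c(TRUE, diff(new_t) > 0) & c(diff(new_t) > 0, TRUE)
  new_t[!ok] <- endpoints$time_s[!ok]
  new_y[!ok] <- endpoints$y_mm[!ok]
  endpoints$time_s <- new_t
  endpoints$y_mm <- new_y
  endpoints
}

#' Anchor detected endpoints to the set boundaries
#'
#' Sets are performed from, and return to, the lowered (eccentric) position,
#' so the first and last samples of a set act as eccentric endpoints even
#' though no reversal confirms them. This prepends the first trace sample as
#' an eccentric endpoint when the first detected endpoint is concentric, and
#' appends the final sample when the last detected endpoint is concentric.
#'
#' @param endpoints Output of [detect_endpoints()].
#' @param trace The trace the endpoints were detected on.
#' @return An `endpoint_events` data.frame with boundary anchors added.
#' @export
anchor_set_endpoints <- function(endpoints, trace) {
  n <- nrow(trace)
  if (n == 0L) return(endpoints)
  if (nrow(endpoints) == 0L) return(endpoints)
  if (endpoints$phase_label[1] == "concentric") {
    endpoints <- rbind(
      new_endpoints(trace$time_s[1], trace$y_mm[1], "eccentric"),
      endpoints)
  }
  m <- nrow(endpoints)
  if (endpoints$phase_label[m] == "concentric") {
    endpoints <- rbind(
      endpoints,
      new_endpoints(trace$time_s[n], trace$y_mm[n], "eccentric"))
  }
  class(endpoints) <- c("endpoint_events", "data.frame")
  endpoints
}

check_alternating <- function(endpoints) {
  lab <- endpoints$phase_label
  if (length(lab) > 1L && any(lab[-1] == lab[-length(lab)])) {
    stop_input("endpoint phase labels must alternate")
  }
  invisible(endpoints)
}

#' Segment alternating endpoints into repetitions
#'
#' One repetition runs from an eccentric endpoint up to the next concentric
#' endpoint (the lifting phase, whose duration is the concentric contraction
#' time) and back down to the following eccentric endpoint (the lowering
#' phase / eccentric contraction time). The trailing eccentric endpoint of
#' each repetition starts the next one; a trailing unpaired endpoint is
#' dropped.
#'
#' @param endpoints An `endpoint_events` data.frame with alternating
#'   `phase_label`s.
#' @return A data.frame of class `repetitions`, one row per repetition:
#'   `index`, `concentric_time_s`, `eccentric_time_s`, `con_time_s`,
#'   `con_y_mm`, `ecc_time_s`, `ecc_y_mm` (the concentric / trailing
#'   eccentric endpoint coordinates).
#' @export
segment_reps <- function(endpoints) {
  check_alternating(endpoints)
  lab <- endpoints$phase_label
  first_ecc <- match("eccentric", lab)
  out <- data.frame(index = integer(), concentric_time_s = numeric(),
                    eccentric_time_s = numeric(), con_time_s = numeric(),
                    con_y_mm = numeric(), ecc_time_s = numeric(),
                    ecc_y_mm = numeric())
  if (!is.na(first_ecc)) {
    i <- first_ecc
    k <- 0L
    while (i + 2L <= nrow(endpoints)) {
      k <- k + 1L
      out <- rbind(out, data.frame(
        index = k,
        concentric_time_s = endpoints$time_s[i + 1] - endpoints$time_s[i],
        eccentric_time_s = endpoints$time_s[i + 2] - endpoints$time_s[i + 1],
        con_time_s = endpoints$time_s[i + 1],
        con_y_mm = endpoints$y_mm[i + 1],
        ecc_time_s = endpoints$time_s[i + 2],
        ecc_y_mm = endpoints$y_mm[i + 2]))
      i <- i + 2L
    }
  }
  structure(out, class = c("repetitions", "data.frame"))
}

#' Per-set exercise-quality metrics
#'
#' Summarises one set: mean and SD of concentric and eccentric contraction
#' times, the within-set variation (sample SD, n-1 denominator) of the
#' concentric and eccentric endpoint positions, and the exhalation count.
#' An empty repetition list yields zero metrics.
#'
#' @param reps Output of [segment_reps()].
#' @param exhalations Integer count of exhalations detected during the set.
#' @return A one-row data.frame of class `set_metrics` with columns
#'   `n_reps`, `mean_con_s`, `sd_con_s`, `mean_ecc_s`, `sd_ecc_s`,
#'   `sd_con_endpoint_mm`, `sd_ecc_endpoint_mm`, `exhalation_count`.
#' @export
set_metrics <- function(reps, exhalations = 0L) {
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  mean0 <- function(x) if (length(x) == 0L) 0 else mean(x)
  structure(data.frame(
    n_reps = nrow(reps),
    mean_con_s = mean0(reps$concentric_time_s),
    sd_con_s = sd0(reps$concentric_time_s),
    mean_ecc_s = mean0(reps$eccentric_time_s),
    sd_ecc_s = sd0(reps$eccentric_time_s),
    sd_con_endpoint_mm = sd0(reps$con_y_mm),
    sd_ecc_endpoint_mm = sd0(reps$ecc_y_mm),
    exhalation_count = as.integer(exhalations)
  ), class = c("set_metrics", "data.frame"))
}

#' Full kinematic analysis of one set
#'
#' Convenience pipeline: smooth the raw trace, detect turning points, anchor
#' the set boundaries, segment repetitions, and compute set metrics.
#'
#' @inheritParams smooth_trace
#' @inheritParams detect_endpoints
#' @param exhalations Exhalation count to carry into the metrics.
#' @return A list with elements `trace` (smoothed), `endpoints`, `reps`,
#'   and `metrics`.
#' @export
analyze_set <- function(raw, params = smoothing_params(),
                        min_half_period_s = 0.5, min_prominence_mm = 20,
                        exhalations = 0L) {
  sm <- smooth_trace(raw, params)
  eps <- detect_endpoints(sm, min_half_period_s, min_prominence_mm)
  eps <- refine_endpoints(eps, raw)
  eps <- anchor_set_endpoints(eps, raw)
  reps <- segment_reps(eps)
  list(trace = sm, endpoints = eps, reps = reps,
       metrics = set_metrics(reps, exhalations))
}
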