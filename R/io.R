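#' Read and write motion-trace CSV files
#'
#' Motion traces are stored as UTF-8 CSV with header `time_s,y_mm`, one row
#' per sample. Trace metadata (exercise kind, origin reference, nominal
#' rate) travels in a JSON sidecar `<path>.json`, written alongside unless
#' disabled.
#'
#' @param trace A [motion_trace()].
#' @param path CSV file path.
#' @param sidecar Write/read the metadata sidecar (default `TRUE`; on read,
#'   a missing sidecar falls back to the defaults).
#' @return `read_motion_csv()` returns a [motion_trace()];
#'   `write_motion_csv()` returns `path` invisibly.
#' @export
write_motion_csv <- function(trace, path, sidecar = TRUE) {
  utils::write.csv(data.frame(time_s = trace$time_s, y_mm = trace$y_mm),
                   path, row.names = FALSE)
  if (sidecar) {
    meta <- list(exercise_kind = attr(trace, "exercise_kind"),
                 origin_ref = attr(trace, "origin_ref"),
                 nominal_rate_hz = attr(trace, "nominal_rate_hz"))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_motion_csv
#' @export
read_motion_csv <- function(path, sidecar = TRUE) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "y_mm") %in% names(d))) {
    stop_input("motion CSV must have columns time_s,y_mm")
  }
  meta <- list(exercise_kind = "bicep_curl", origin_ref = NULL,
               nominal_rate_hz = 30)
  side <- paste0(path, ".json")
  if (sidecar && file.exists(side)) {
    got <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  motion_trace(d$time_s, d$y_mm, exercise_kind = meta$exercise_kind,
               origin_ref = meta$origin_ref,
               nominal_rate_hz = meta$nominal_rate_hz)
}

#' Read and write breath-envelope CSV files
#'
#' UTF-8 CSV with header `time_s,amplitude`.
#'
#' @param env A [breath_envelope()].
#' @param path CSV file path.
#' @return `read_envelope_csv()` returns a [breath_envelope()].
#' @export
write_envelope_csv <- function(env, path) {
  utils::write.csv(data.frame(time_s = env$time_s, amplitude = env$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(d))) {
    stop_input("envelope CSV must have columns time_s,amplitude")
  }
  breath_envelope(d$time_s, d$amplitude)
}

#' Read and write the calibration JSON
#'
#' `{"y_ecc_mm": ..., "y_con_mm": ..., "tolerance_mm": ...}`.
#'
#' @param cal A [calibration_profile()].
#' @param path JSON file path.
#' @return `read_calibration_json()` returns a [calibration_profile()].
#' @export
write_calibration_json <- function(cal, path) {
  jsonlite::write_json(list(y_ecc_mm = cal$y_ecc_mm, y_con_mm = cal$y_con_mm,
                            tolerance_mm = cal$tolerance_mm),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_profile(d$y_ecc_mm, d$y_con_mm,
                      if (is.null(d$tolerance_mm)) 20 else d$tolerance_mm)
}

#' Read and write feedback event logs (JSON lines)
#'
#' One event per line: `time_s`, `kind`, and a `payload` object holding any
#' non-missing detail fields (`pitch_hz`, `timing_error_s`, `rom_class`).
#'
#' @param events A `feedback_events` data.frame.
#' @param path JSONL file path.
#' @return `read_events_jsonl()` returns a `feedback_events` data.frame.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    payload <- list()
    if (!is.na(events$pitch_hz[i])) payload$pitch_hz <- events$pitch_hz[i]
    if (!is.na(events$timing_error_s[i])) {
      payload$timing_error_s <- events$timing_error_s[i]
    }
    if (!is.na(events$rom_class[i])) payload$rom_class <- events$rom_class[i]
    line <- jsonlite::toJSON(list(time_s = events$time_s[i],
                                  kind = events$kind[i], payload = payload),
                             auto_unbox = TRUE, digits = NA)
    writeLines(line, con)
  }
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- new_events()
  for (ln in lines) {
    d <- jsonlite::fromJSON(ln)
    p <- d$payload
    grab <- function(nm) {
      if (!is.null(p[[nm]])) p[[nm]] else NA
    }
    out <- rbind(out, new_events(d$time_s, d$kind,
                                 as.numeric(grab("pitch_hz")),
                                 as.numeric(grab("timing_error_s")),
                                 as.character(grab("rom_class"))))
  }
  class(out) <- c("feedback_events", "data.frame")
  out
}

#' Write per-set metrics to CSV
#'
#' One row per set with the [set_metrics()] columns.
#'
#' @param metrics A `set_metrics` data.frame (one or more rows, e.g. the
#'   `per_set` table from [summarize_sets()]).
#' @param path CSV file path.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for respiration recordings: supports
#' uncompressed integer PCM (8/16/24/32-bit) and IEEE float (32/64-bit),
#' any sample rate; multi-channel input is downmixed to mono by averaging.
#' Samples are returned normalised to `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return A list with `samples` (numeric vector) and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_input("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_input("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_input("WAV data chunk before fmt chunk")
      bytes <- fmt$bits / 8
      n <- sz %/% bytes
      if (fmt$audio_format == 3L) {
        samples <- readBin(con, "double", n, bytes, endian = "little")
      } else if (fmt$audio_format == 1L) {
        if (fmt$bits == 8L) {
          samples <- (readBin(con, "integer", n, 1, signed = FALSE) - 128) / 128
        } else if (fmt$bits == 24L) {
          raw <- readBin(con, "raw", sz)
          m <- matrix(as.integer(raw[seq_len(n * 3)]), nrow = 3)
          v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
          v <- ifelse(v >= 8388608, v - 16777216, v)
          samples <- v / 8388608
        } else {
          samples <- readBin(con, "integer", n, bytes, signed = TRUE,
                             endian = "little") / 2^(fmt$bits - 1)
        }
      } else {
        stop_input("unsupported WAV audio format code ", fmt$audio_format)
      }
      if (sz %% 2 == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop_input("no data chunk found in ", path)
  if (fmt$n_channels > 1L) {
    usable <- length(samples) - length(samples) %% fmt$n_channels
    samples <- colMeans(matrix(samples[seq_len(usable)],
                               nrow = fmt$n_channels))
  }
  list(samples = as.numeric(samples), sample_rate_hz = fmt$sample_rate)
}
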