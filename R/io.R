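# File interchange: plain-text CSV for traces, calibration data, spikes and
# trial tables; multi-page TIFF (+ JSON sidecar) for movies when the optional
# readers are installed.

#' Read and write sampled traces as CSV
#'
#' Trace CSVs carry a `time_s` column plus one column per channel; the
#' sampling rate is recovered from the time stamps on read.
#'
#' @param path File path.
#' @param traces Data frame with a `time_s` column.
#' @return `read_trace_csv()` returns a tibble with attribute `fs`.
#' @export
read_trace_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  if (!"time_s" %in% names(df)) abort("trace CSV must have a `time_s` column.")
  attr(df, "fs") <- 1 / median(diff(df$time_s))
  df
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(traces, path) {
  write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' Read a probe calibration CSV (`position_um,force_uN`)
#'
#' @param path File path.
#' @return A tibble ready for [calibrate_spring_constant()].
#' @export
read_calibration_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  if (!all(c("position_um", "force_uN") %in% names(df))) {
    abort("calibration CSV must have columns position_um, force_uN.")
  }
  df
}

#' Write detected spikes as CSV
#'
#' Columns: `peak_s`, `onset_s`, `amplitude`, `shape_distance`.
#'
#' @param spikes An `fm_spikes` tibble.
#' @param path File path.
#' @export
write_spikes_csv <- function(spikes, path) {
  write.csv(
    spikes[, c("peak_s", "onset_s", "amplitude", "shape_distance")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read/write tracked leg points as a wide CSV
#'
#' Wide layout: `frame, x_f1..x_f6, y_f1..y_f6, x_t1..x_t6, y_t1..y_t6`.
#'
#' @param points Long tibble (`frame`, `role`, `idx`, `x`, `y`).
#' @param path File path.
#' @return `read_tracked_csv()` returns the long tibble.
#' @export
write_tracked_csv <- function(points, path) {
  wide <- points |>
    dplyr::filter(.data$role %in% c("femur", "tibia")) |>
    dplyr::mutate(tag = paste0(substr(.data$role, 1L, 1L), .data$idx)) |>
    dplyr::select("frame", "tag", "x", "y") |>
    tidyr::pivot_wider(names_from = "tag", values_from = c("x", "y"))
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracked_csv
#' @export
read_tracked_csv <- function(path) {
  wide <- tibble::as_tibble(read.csv(path))
  long <- wide |>
    tidyr::pivot_longer(-"frame", names_to = c("coord", "tag"),
                        names_pattern = "([xy])_([ft][0-9])") |>
    tidyr::pivot_wider(names_from = "coord", values_from = "value")
  long$role <- ifelse(substr(long$tag, 1L, 1L) == "f", "femur", "tibia")
  long$idx <- as.integer(substr(long$tag, 2L, 2L))
  long[, c("frame", "role", "idx", "x", "y")]
}

#' Write a behavioral trial table as CSV
#'
#' Columns `trial_id, group, stim_ms, category, outcome` (speed traces are
#' not serialised).
#'
#' @param trials A trial table (e.g. from [simulate_behavior_trials()]).
#' @param path File path.
#' @export
write_trials_csv <- function(trials, path) {
  write.csv(
    trials[, c("trial_id", "group", "stim_ms", "category", "outcome")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write/read a movie as multi-page TIFF with a JSON sidecar
#'
#' Requires the optional `tiff` and `jsonlite` packages. Pixel values are
#' rescaled to `[0, 1]` for TIFF storage; the scale, frame times and
#' pixel size are recorded in the sidecar (`<path>.json`).
#'
#' @param movie An `fm_movie`.
#' @param path TIFF file path.
#' @param pixel_size_um2 Pixel area recorded in the sidecar.
#' @return `read_movie_tiff()` returns a list with `frames`, `times_s`,
#'   `fps`.
#' @export
write_movie_tiff <- function(movie, path, pixel_size_um2 = 1.03) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE)) {
    abort("TIFF export needs the `tiff` and `jsonlite` packages.")
  }
  fr <- movie$frames
  lo <- min(fr); hi <- max(fr)
  scl <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(fr)[3]), function(i) (fr[, , i] - lo) / scl)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(times_s = movie$times_s, fps = movie$fps,
         pixel_size_um2 = pixel_size_um2, offset = lo, scale = scl),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE)) {
    abort("TIFF import needs the `tiff` and `jsonlite` packages.")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fr <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) fr[, , i] <- pages[[i]] * meta$scale + meta$offset
  list(frames = fr, times_s = meta$times_s, fps = meta$fps)
}
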