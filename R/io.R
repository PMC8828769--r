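# Plain-text persistence: movies as per-channel CSV matrices (frames x
# pixels) with a JSON sidecar; EMG as a two-column CSV plus JSON stimulus
# intervals. No binary container is used so artifacts stay inspectable.

#' Write / read a synthetic movie as CSV + JSON sidecar
#'
#' Each channel is written as a headerless CSV with one row per frame and
#' one column per pixel (column-major pixel order); the sidecar records the
#' dimensions, frame rate and stimulus onsets.
#'
#' @param movie An [imaging_movie()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the three files.
#' @return `write_movie()`: the sidecar path, invisibly.
#' @export
write_movie <- function(movie, dir, name = "movie") {
  stopifnot(inherits(movie, "imaging_movie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(movie)
  for (ch in c("segmentation", "activity")) {
    m <- t(matrix(movie[[ch]], d[1] * d[2], d[3]))
    utils::write.table(m, file.path(dir, sprintf("%s_%s.csv", name, ch)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(height_px = d[1], width_px = d[2], n_frames = d[3],
         frame_rate_hz = movie$frame_rate_hz,
         stimulus_onsets_s = movie$stimulus_onsets_s),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_movie
#' @return `read_movie()`: the reconstructed [imaging_movie()].
#' @export
read_movie <- function(dir, name = "movie") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  get_ch <- function(ch) {
    m <- as.matrix(utils::read.csv(
      file.path(dir, sprintf("%s_%s.csv", name, ch)), header = FALSE))
    array(t(m), dim = c(meta$height_px, meta$width_px, meta$n_frames))
  }
  imaging_movie(get_ch("segmentation"), get_ch("activity"),
                frame_rate_hz = meta$frame_rate_hz,
                stimulus_onsets_s = meta$stimulus_onsets_s)
}

#' Write / read an EMG recording as CSV + JSON
#'
#' @param recording An `emg_recording`.
#' @param path CSV path (`time_s`, `volts`); the stimulus intervals go to a
#'   JSON file alongside (same path with extension `.json`).
#' @return `write_emg()`: the CSV path, invisibly.
#' @export
write_emg <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  tt <- (seq_along(recording$volts) - 1) / recording$sampling_rate_hz
  utils::write.csv(data.frame(time_s = tt, volts = recording$volts),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate_hz = recording$sampling_rate_hz,
         stimulus_intervals_s = unname(split(
           recording$stimulus_intervals_s,
           seq_len(nrow(recording$stimulus_intervals_s))))),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_emg
#' @return `read_emg()`: the reconstructed `emg_recording`.
#' @export
read_emg <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  iv <- meta$stimulus_intervals_s
  iv <- if (is.list(iv)) do.call(rbind, lapply(iv, as.numeric)) else
    matrix(as.numeric(iv), ncol = 2)
  structure(list(sampling_rate_hz = meta$sampling_rate_hz,
                 volts = df$volts, stimulus_intervals_s = iv),
            class = "emg_recording")
}
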