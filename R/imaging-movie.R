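#' Two-channel imaging movie container
#'
#' Bundles the segmentation (marker) and activity (calcium) channels of one
#' acquisition as `H x W x T` numeric arrays together with the frame rate and
#' stimulus onset times. The two channels must share a shape; onsets must fall
#' inside the recording.
#'
#' @param segmentation,activity `H x W x T` non-negative numeric arrays.
#' @param frame_rate_hz Frames per second.
#' @param stimulus_onsets_s Stimulus onset times in seconds.
#' @return An `imaging_movie` object.
#' @export
imaging_movie <- function(segmentation, activity, frame_rate_hz,
                          stimulus_onsets_s = numeric()) {
  if (!is.array(segmentation) || length(dim(segmentation)) != 3L ||
      !is.array(activity) || length(dim(activity)) != 3L) {
    abort("Channels must be H x W x T numeric arrays.")
  }
  if (!identical(dim(segmentation), dim(activity))) {
    abort("Both channels must have identical dimensions.")
  }
  check_number(frame_rate_hz, "frame_rate_hz", 1e-6)
  nt <- dim(activity)[3]
  if (any(stimulus_onsets_s < 0 | stimulus_onsets_s >= nt / frame_rate_hz)) {
    abort("Stimulus onsets must lie within the recording.")
  }
  structure(
    list(segmentation = segmentation, activity = activity,
         frame_rate_hz = frame_rate_hz,
         stimulus_onsets_s = sort(as.numeric(stimulus_onsets_s))),
    class = "imaging_movie")
}

#' @export
print.imaging_movie <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("<imaging_movie> %d x %d px, %d frames @ %.1f fps, %d stimuli\n",
              d[1], d[2], d[3], x$frame_rate_hz, length(x$stimulus_onsets_s)))
  invisible(x)
}

#' @export
dim.imaging_movie <- function(x) dim(x$activity)

#' Frame times of a movie
#'
#' @param movie An [imaging_movie()].
#' @return Times (s) of frame centres; frame `t` is taken at `(t - 1) / rate`.
#' @export
frame_times <- function(movie) {
  (seq_len(dim(movie)[3]) - 1) / movie$frame_rate_hz
}

#' Pixel set of a planted cell
#'
#' Linear pixel indices (column-major, `H x W` grid) of the hard disk of a
#' planted cell; the per-pixel oracle for synthetic movies.
#'
#' @param row,col Cell centre (1-based pixel coordinates).
#' @param radius Disk radius (px).
#' @param height_px,width_px Field size.
#' @return Integer vector of linear pixel indices.
#' @export
cell_pixels <- function(row, col, radius, height_px, width_px) {
  r0 <- max(1L, floor(row - radius)); r1 <- min(height_px, ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(width_px, ceiling(col + radius))
  rr <- r0:r1; cc <- c0:c1
  grid <- expand.grid(r = rr, c = cc)
  keep <- (grid$r - row)^2 + (grid$c - col)^2 <= radius^2
  as.integer(grid$r[keep] + (grid$c[keep] - 1L) * height_px)
}
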