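#' Segmentation configuration
#'
#' Parameters for the marker-channel ROI extraction chain: Gaussian filter,
#' background subtraction (morphological opening), Otsu auto-threshold, then
#' distance-transform watershed to split touching cells, with an area filter.
#'
#' @param gaussian_sigma_px Gaussian filter sigma (px), default 2.
#' @param background_radius_px Structuring-element radius (px) for the
#'   opening-based background estimate, default 50.
#' @param min_area_px,max_area_px ROI area bounds in pixels.
#' @param watershed_min_sep_px Minimum separation (px) between watershed
#'   seeds; roughly the smallest expected cell diameter.
#' @return A `seg_config` list.
#' @export
seg_config <- function(gaussian_sigma_px = 2, background_radius_px = 50,
                       min_area_px = 20, max_area_px = 2500,
                       watershed_min_sep_px = 8) {
  check_number(gaussian_sigma_px, "gaussian_sigma_px", 0)
  check_number(background_radius_px, "background_radius_px", 1)
  check_number(min_area_px, "min_area_px", 0)
  check_number(max_area_px, "max_area_px", min_area_px)
  check_number(watershed_min_sep_px, "watershed_min_sep_px", 1)
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 background_radius_px = background_radius_px,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 watershed_min_sep_px = watershed_min_sep_px),
            class = "seg_config")
}

#' Segment cells on the marker channel
#'
#' Applies, in order, on the temporal median frame of the segmentation
#' (dTomato) channel: Gaussian filter, background subtraction, Otsu
#' auto-threshold, distance-transform watershed, then an ROI area filter.
#' The temporal median is used because the marker channel is static up to
#' noise; transients never contaminate it.
#'
#' @param movie An [imaging_movie()].
#' @param cfg A [seg_config()].
#' @return An object of class `roi_set`: list with `labels` (`H x W` integer
#'   label image, 0 = background) and `rois` (tibble with `roi`, `row`, `col`
#'   centroid and `area_px`). An image with no detectable cells yields zero
#'   ROIs, not an error.
#' @examples
#' sim <- simulate_movie(movie_plan(n_cells = 4, duration_s = 10, seed = 2))
#' rois <- segment_cells(sim$movie)
#' rois$rois
#' @export
segment_cells <- function(movie, cfg = seg_config()) {
  stopifnot(inherits(movie, "imaging_movie"), inherits(cfg, "seg_config"))
  ref <- apply(movie$segmentation, c(1, 2), median)
  if (anyNA(ref) || any(!is.finite(ref))) {
    abort("Segmentation channel contains NaN/non-finite pixels.")
  }
  sm <- gaussian_blur(ref, cfg$gaussian_sigma_px)
  bg <- grey_opening(sm, as.integer(cfg$background_radius_px))
  fg <- sm - bg
  if (diff(range(fg)) == 0) {
    return(roi_set(matrix(0L, nrow(ref), ncol(ref))))
  }
  thr <- otsu_threshold(fg)
  # guard against signal-free fields: Otsu always splits the histogram, so
  # require the threshold to stand clear of the background noise floor
  noise_floor <- median(fg) + 3 * stats::mad(fg)
  if (thr <= noise_floor) {
    return(roi_set(matrix(0L, nrow(ref), ncol(ref))))
  }
  mask <- fg > thr
  labels <- watershed_labels(mask, cfg$watershed_min_sep_px)
  # area filter, then relabel 1..K
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= cfg$min_area_px & areas <= cfg$max_area_px)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  roi_set(labels)
}

#' Construct an ROI set from a label image
#'
#' @param labels `H x W` integer matrix, 0 = background, `k` = ROI `k`.
#' @return A `roi_set` with the label image and per-ROI centroid/area table.
#' @export
roi_set <- function(labels) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  k <- max(labels, 0L)
  if (k == 0L) {
    rois <- tibble(roi = integer(), row = numeric(), col = numeric(),
                   area_px = integer())
  } else {
    idx <- which(labels > 0L)
    h <- nrow(labels)
    df <- tibble(roi = labels[idx],
                 row = ((idx - 1L) %% h) + 1L,
                 col = ((idx - 1L) %/% h) + 1L)
    rois <- df |>
      dplyr::group_by(.data$roi) |>
      dplyr::summarise(row = mean(.data$row), col = mean(.data$col),
                       area_px = dplyr::n(), .groups = "drop")
  }
  structure(list(labels = labels, rois = rois), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs on a %d x %d field\n",
              nrow(x$rois), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Pixel indices of one ROI
#'
#' @param rois A [roi_set()].
#' @param roi ROI id.
#' @return Linear pixel indices (column-major).
#' @export
roi_pixels <- function(rois, roi) {
  which(rois$labels == roi)
}

#' Extract per-ROI fluorescence traces
#'
#' For every ROI, the frame-`t` value is the arithmetic mean of the chosen
#' channel over the ROI's pixels at frame `t`.
#'
#' @param movie An [imaging_movie()].
#' @param rois A [roi_set()]; every ROI must lie inside the field.
#' @param channel `"activity"` (default) or `"segmentation"`.
#' @return A tibble in long format: `roi`, `frame` (1-based), `time_s`,
#'   `value`.
#' @export
extract_traces <- function(movie, rois, channel = c("activity", "segmentation")) {
  stopifnot(inherits(movie, "imaging_movie"), inherits(rois, "roi_set"))
  channel <- match.arg(channel)
  d <- dim(movie)
  if (!identical(dim(rois$labels), d[1:2])) {
    abort("ROI label image does not match the movie field size.")
  }
  arr <- movie[[channel]]
  nt <- d[3]
  mat <- matrix(arr, d[1] * d[2], nt)
  ids <- rois$rois$roi
  out <- purrr::map_dfr(ids, function(k) {
    px <- roi_pixels(rois, k)
    if (!length(px)) abort(sprintf("ROI %d is empty.", k))
    tibble(roi = k, frame = seq_len(nt),
           time_s = (seq_len(nt) - 1) / movie$frame_rate_hz,
           value = colMeans(mat[px, , drop = FALSE]))
  })
  out
}

#' Fraction of transfected cells
#'
#' Marker-positive cell count over the total cell count in the field of view
#' (the denominator is supplied by the caller, e.g. a manual count or a
#' second segmentation of the activity-channel baseline).
#'
#' @param roi_marker A [roi_set()] from the marker channel, or an integer
#'   count of marker-positive cells.
#' @param total_cells Total number of cells in the field; must be at least
#'   the marker count and positive.
#' @return Fraction in `[0, 1]`.
#' @export
percent_transfected <- function(roi_marker, total_cells) {
  n_marker <- if (inherits(roi_marker, "roi_set")) nrow(roi_marker$rois)
              else check_number(roi_marker, "roi_marker", 0)
  check_number(total_cells, "total_cells", 1)
  if (total_cells < n_marker) {
    abort("`total_cells` must be at least the marker-positive count.")
  }
  n_marker / total_cells
}
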