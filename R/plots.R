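#' Plot an ROI label image
#'
#' @param object A [roi_set()].
#' @param ... Unused.
#' @return A ggplot: label image with ROI centroids marked.
#' @export
autoplot.roi_set <- function(object, ...) {
  lab <- object$labels
  df <- tibble(row = rep(seq_len(nrow(lab)), ncol(lab)),
               col = rep(seq_len(ncol(lab)), each = nrow(lab)),
               roi = as.vector(lab))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$roi))) +
    ggplot2::geom_point(data = object$rois, shape = 3, colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = sprintf("%d ROIs", nrow(object$rois)))
}

#' Plot dF/F traces with responder calls
#'
#' @param dff Tibble from [compute_dff()].
#' @param calls Optional tibble from [call_response()]; colours traces by
#'   the responder flag and marks the threshold.
#' @param stimulus_onset_s Optional onset marked with a vertical line.
#' @return A ggplot of dF/F against time, one line per ROI.
#' @export
plot_dff_traces <- function(dff, calls = NULL, stimulus_onset_s = NULL) {
  df <- dff
  p <- if (!is.null(calls)) {
    df <- dplyr::left_join(df, calls[, c("roi", "responsive")], by = "roi")
    ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$dff,
                                     group = .data$roi,
                                     colour = .data$responsive))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$dff,
                                     group = .data$roi))
  }
  p <- p + ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F))
  if (!is.null(calls)) {
    p <- p + ggplot2::geom_hline(yintercept = calls$threshold[1],
                                 linetype = "dashed")
  }
  if (!is.null(stimulus_onset_s)) {
    p <- p + ggplot2::geom_vline(xintercept = stimulus_onset_s,
                                 colour = "orange")
  }
  p
}

#' Plot a dose-response table
#'
#' @param tbl Output of [dose_response_table()] (first column = dose level).
#' @param hill Optional named list `(pmax, ec50, hill)` to overlay the
#'   generating Hill curve.
#' @return A ggplot of responsive fraction vs dose with exact binomial CIs.
#' @export
plot_dose_response <- function(tbl, hill = NULL) {
  dose_col <- names(tbl)[1]
  p <- ggplot2::ggplot(tbl, ggplot2::aes(.data[[dose_col]], .data$fraction)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = dose_col, y = "responsive fraction") +
    ggplot2::ylim(0, 1)
  if (!is.null(hill)) {
    xx <- seq(min(tbl[[dose_col]]), max(tbl[[dose_col]]), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(x = xx,
                    fraction = hill_response(xx, hill$pmax, hill$ec50,
                                             hill$hill)),
      ggplot2::aes(.data$x, .data$fraction), colour = "steelblue")
  }
  p
}

#' Forest plot of pairwise odds ratios
#'
#' @param contrasts Tibble from [pairwise_odds_ratios()].
#' @return A ggplot of ORs with family-wise confidence intervals (log scale).
#' @export
plot_odds_ratios <- function(contrasts) {
  ggplot2::ggplot(contrasts,
                  ggplot2::aes(.data$odds_ratio, .data$contrast)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (Tukey-adjusted CI)", y = NULL)
}

#' Plot an EMG recording with detected events
#'
#' @param recording An `emg_recording`.
#' @param events Optional tibble from [detect_emg_events()].
#' @param downsample Plot every n-th sample (default 10) to keep the figure
#'   light at 40 kHz.
#' @return A ggplot of voltage against time, stimulus intervals shaded and
#'   event onsets marked.
#' @export
plot_emg <- function(recording, events = NULL, downsample = 10L) {
  idx <- seq(1, length(recording$volts), by = downsample)
  df <- tibble(time_s = (idx - 1) / recording$sampling_rate_hz,
               volts = recording$volts[idx])
  iv <- as.data.frame(recording$stimulus_intervals_s)
  names(iv) <- c("on", "off")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$volts)) +
    ggplot2::geom_rect(data = iv,
                       ggplot2::aes(xmin = .data$on, xmax = .data$off,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "orange", alpha = 0.3) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "EMG (V)")
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_vline(xintercept = events$onset_s,
                                 colour = "red", linetype = "dotted")
  }
  p
}
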