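#' dF/F normalisation of fluorescence traces
#'
#' For each ROI, the baseline F0 is the mean fluorescence over the
#' `baseline_window_s` seconds immediately preceding the (first) stimulus
#' onset; dF/F(t) = (F(t) - F0) / F0. A constant positive trace therefore
#' maps to identically zero.
#'
#' @param traces Long tibble from [extract_traces()]: columns `roi`,
#'   `time_s`, `value` (and optionally `frame`).
#' @param stimulus_onset_s Stimulus onset time (s); at least
#'   `baseline_window_s` of pre-stimulus data must exist.
#' @param baseline_window_s Baseline window length (s), default 6.
#' @return Tibble: `roi`, `frame`, `time_s`, `dff`, `f0`.
#' @examples
#' tr <- tibble::tibble(roi = 1, frame = 1:100,
#'                      time_s = (0:99) / 10, value = 100)
#' compute_dff(tr, stimulus_onset_s = 7, baseline_window_s = 6)
#' @export
compute_dff <- function(traces, stimulus_onset_s, baseline_window_s = 6) {
  stopifnot(all(c("roi", "time_s", "value") %in% names(traces)))
  check_number(stimulus_onset_s, "stimulus_onset_s", 0)
  check_number(baseline_window_s, "baseline_window_s", 1e-9)
  if (stimulus_onset_s - baseline_window_s < -1e-9) {
    abort("Not enough pre-stimulus data for the baseline window.")
  }
  if (!"frame" %in% names(traces)) {
    traces <- traces |> dplyr::group_by(.data$roi) |>
      dplyr::mutate(frame = dplyr::row_number()) |> dplyr::ungroup()
  }
  out <- traces |>
    dplyr::group_by(.data$roi) |>
    dplyr::mutate(f0 = {
      inb <- .data$time_s >= (stimulus_onset_s - baseline_window_s) &
        .data$time_s < stimulus_onset_s
      if (!any(inb)) abort("Baseline window contains no frames.")
      mean(.data$value[inb])
    }) |>
    dplyr::ungroup()
  if (any(out$f0 <= 0)) {
    abort("Non-physical baseline: F0 <= 0 for at least one ROI.")
  }
  out |>
    dplyr::mutate(dff = (.data$value - .data$f0) / .data$f0) |>
    dplyr::select("roi", "frame", "time_s", "dff", "f0")
}

#' Fixed-threshold responder calling
#'
#' Classifies each ROI by its peak dF/F in the post-stimulus analysis window
#' `(onset, onset + window_s]`: responsive iff the peak reaches the fixed
#' threshold (default 0.25). The window default depends on the preparation:
#' 60 s for HEK-like recordings, 5 s for primary neurons.
#'
#' @param dff Tibble from [compute_dff()].
#' @param stimulus_onset_s Stimulus onset (s).
#' @param window_s Analysis window length (s); must be positive and fit in
#'   the trace.
#' @param threshold Responder threshold on peak dF/F (default 0.25);
#'   comparison is `>=`.
#' @return Tibble, one row per ROI: `roi`, `responsive`, `threshold`,
#'   `peak_amplitude`, `peak_time_s` (earliest frame attaining the max),
#'   `window_s`.
#' @export
call_response <- function(dff, stimulus_onset_s, window_s = 60,
                          threshold = 0.25) {
  check_number(window_s, "window_s", 1e-12)
  check_number(threshold, "threshold")
  tmax <- max(dff$time_s)
  if (stimulus_onset_s + window_s > tmax + 1e-9) {
    abort("Analysis window does not fit within the trace.")
  }
  dff |>
    dplyr::filter(.data$time_s > stimulus_onset_s,
                  .data$time_s <= stimulus_onset_s + window_s) |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      peak_amplitude = max(.data$dff),
      peak_time_s = .data$time_s[which.max(.data$dff)],
      .groups = "drop") |>
    dplyr::mutate(responsive = .data$peak_amplitude >= threshold,
                  threshold = threshold, window_s = window_s) |>
    dplyr::select("roi", "responsive", "threshold", "peak_amplitude",
                  "peak_time_s", "window_s")
}

#' Rise latency and width at 63% of peak
#'
#' Latency is the first time after the stimulus at which dF/F reaches 63% of
#' the peak amplitude; width is the time from that rising crossing to the
#' first post-peak falling crossing of the same level. Crossings are located
#' by linear interpolation between frames (the frame period, 1/16.6 s, is
#' coarse relative to the kinetics). If the trace never decays back below
#' the 63% level, the width is censored (`width_censored = TRUE`) with the
#' width measured to the end of the trace.
#'
#' @param dff Tibble from [compute_dff()] (may hold many ROIs).
#' @param calls Tibble from [call_response()]; only responsive ROIs are
#'   measured.
#' @param stimulus_onset_s Stimulus onset (s).
#' @param level Fraction of peak used for the crossings, default 0.63.
#' @return Tibble: `roi`, `latency_s`, `width_s`, `width_censored`.
#' @export
latency_and_width <- function(dff, calls, stimulus_onset_s, level = 0.63) {
  check_fraction(level, "level")
  resp <- calls |> dplyr::filter(.data$responsive)
  purrr::map_dfr(seq_len(nrow(resp)), function(i) {
    id <- resp$roi[i]
    tr <- dff |> dplyr::filter(.data$roi == id,
                               .data$time_s >= stimulus_onset_s)
    target <- level * resp$peak_amplitude[i]
    up <- crossing_time(tr$time_s, tr$dff, target, rising = TRUE)
    if (is.na(up)) {
      return(tibble(roi = id, latency_s = NA_real_, width_s = NA_real_,
                    width_censored = NA))
    }
    post_peak <- tr$time_s >= resp$peak_time_s[i]
    down <- crossing_time(tr$time_s[post_peak], tr$dff[post_peak], target,
                          rising = FALSE)
    censored <- is.na(down)
    if (censored) down <- max(tr$time_s)
    tibble(roi = id,
           latency_s = up - stimulus_onset_s,
           width_s = down - up,
           width_censored = censored)
  })
}

# First time the series crosses `target` in the given direction, linearly
# interpolated; NA if never. Series sampled at times `tt`.
crossing_time <- function(tt, x, target, rising = TRUE) {
  if (!length(x)) return(NA_real_)
  if (rising) {
    hit <- which(x >= target)
    if (!length(hit)) return(NA_real_)
    i <- hit[1]
    if (i == 1L || x[i - 1L] >= target) return(tt[i])
  } else {
    hit <- which(x < target)
    if (!length(hit)) return(NA_real_)
    i <- hit[1]
    if (i == 1L) return(tt[i])
  }
  x0 <- x[i - 1L]; x1 <- x[i]
  if (x1 == x0) return(tt[i])
  tt[i - 1L] + (target - x0) / (x1 - x0) * (tt[i] - tt[i - 1L])
}

#' Percent responsive over repeated recordings
#'
#' A cell counts as responsive if it is responsive in at least one of the
#' consecutive recordings on the same coverslip (union semantics: the
#' quantity is the percent of *cells* that ever responded). A pooled mode
#' treating each (cell, recording) trial as one observation is available.
#'
#' @param calls_list List of call tibbles (one per recording, same ROI ids;
#'   typically 3 consecutive 90-s recordings).
#' @param mode `"union"` (default) or `"pooled"`.
#' @return Fraction in `[0, 1]`.
#' @export
percent_responsive <- function(calls_list, mode = c("union", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(length(calls_list) >= 1)
  ids <- lapply(calls_list, function(x) sort(x$roi))
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
    abort("All recordings must cover the same ROI set.")
  }
  if (mode == "union") {
    resp <- Reduce(`|`, lapply(calls_list, function(x) {
      x$responsive[order(x$roi)]
    }))
    mean(resp)
  } else {
    mean(unlist(lapply(calls_list, function(x) x$responsive)))
  }
}

#' Mean response profile under repeated stimulation
#'
#' Segments dF/F traces into cycles around regularly repeated stimuli
#' (e.g. one pulse every 10 s), averages across ROIs per time point, and
#' reports the per-cycle peak of the mean response. Useful for checking that
#' responses return toward baseline between pulses and whether amplitudes
#' run down across repeats.
#'
#' @param dff Tibble from [compute_dff()].
#' @param onsets_s Stimulus onsets (s), at least two, separated by at least
#'   `window_s`.
#' @param window_s Cycle window after each onset (s); defaults to the
#'   smallest inter-onset interval.
#' @return A list with `profile` (tibble: `cycle`, `t_rel_s`, `mean_dff`)
#'   and `cycle_peaks` (tibble: `cycle`, `peak`, `end_dff` — mean dF/F at
#'   cycle end, for the return-to-baseline check).
#' @export
repeated_stim_profile <- function(dff, onsets_s, window_s = NULL) {
  onsets_s <- sort(onsets_s)
  if (length(onsets_s) < 2) abort("Need at least two stimulus onsets.")
  gap <- min(diff(onsets_s))
  window_s <- window_s %||% gap
  if (window_s > gap + 1e-9) {
    abort("Stimulus onsets are closer together than the analysis window.")
  }
  profile <- purrr::map_dfr(seq_along(onsets_s), function(k) {
    dff |>
      dplyr::filter(.data$time_s >= onsets_s[k],
                    .data$time_s < onsets_s[k] + window_s) |>
      dplyr::group_by(.data$time_s) |>
      dplyr::summarise(mean_dff = mean(.data$dff), .groups = "drop") |>
      dplyr::mutate(cycle = k, t_rel_s = .data$time_s - onsets_s[k]) |>
      dplyr::select("cycle", "t_rel_s", "mean_dff")
  })
  cycle_peaks <- profile |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(peak = max(.data$mean_dff),
                     end_dff = .data$mean_dff[which.max(.data$t_rel_s)],
                     .groups = "drop")
  list(profile = profile, cycle_peaks = cycle_peaks)
}

#' Mean dF/F after agonist addition
#'
#' For slow pharmacological responses (e.g. AITC), the readout is the mean
#' dF/F over the 90 s following compound addition rather than a peak.
#'
#' @param dff Tibble from [compute_dff()].
#' @param t_add_s Addition time (s).
#' @param window_s Averaging window (s), default 90 (1.5 min).
#' @return Tibble: `roi`, `mean_dff`.
#' @export
mean_agonist_response <- function(dff, t_add_s, window_s = 90) {
  check_number(t_add_s, "t_add_s", 0)
  check_number(window_s, "window_s", 1e-9)
  if (t_add_s + window_s > max(dff$time_s) + 1e-9) {
    abort("Insufficient data after the addition time.")
  }
  dff |>
    dplyr::filter(.data$time_s > t_add_s,
                  .data$time_s <= t_add_s + window_s) |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(mean_dff = mean(.data$dff), .groups = "drop")
}
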