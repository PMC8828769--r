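# EMG response detection: band-pass filtering, RMS envelope, threshold
# crossing after stimulus offset (stimulus-coincident artifacts excluded).

# --- Butterworth band-pass (second-order sections) -------------------------

# Design an order-`n` Butterworth band-pass as biquad sections via the
# analog prototype -> band-pass transform -> bilinear transform route.
# Returns list(sections = list of list(b, a), gain).
butter_bandpass_sos <- function(lo_hz, hi_hz, fs, n = 4L) {
  if (hi_hz <= lo_hz) abort("`hi_hz` must exceed `lo_hz`.")
  if (hi_hz >= fs / 2) abort("`hi_hz` must be below the Nyquist frequency.")
  # pre-warped analog band edges
  w1 <- 2 * fs * tan(pi * lo_hz / fs)
  w2 <- 2 * fs * tan(pi * hi_hz / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left half-plane poles
  # band-pass transform: each prototype pole -> two analog poles
  poles <- unlist(lapply(proto, function(p) {
    disc <- sqrt((p * bw)^2 - 4 * w0^2)
    c((p * bw + disc) / 2, (p * bw - disc) / 2)
  }))
  zpoles <- (2 * fs + poles) / (2 * fs - poles)  # bilinear
  # keep one of each conjugate pair (positive imaginary part)
  zp <- zpoles[order(-Im(zpoles))][seq_len(n)]
  sections <- lapply(zp, function(p) {
    list(b = c(1, 0, -1),  # zeros at z = 1 and z = -1
         a = c(1, -2 * Re(p), Mod(p)^2))
  })
  # normalise to unit gain at the (digital) centre frequency
  wc <- 2 * pi * sqrt(lo_hz * hi_hz) / fs
  z <- exp(1i * wc)
  h <- prod(vapply(sections, function(s) {
    abs(sum(s$b * z^(0:-2)) / sum(s$a * z^(0:-2)))
  }, numeric(1)))
  list(sections = sections, gain = 1 / h)
}

# One biquad, direct form, zero initial state.
biquad_filter <- function(x, b, a) {
  v <- stats::filter(c(0, 0, x), b, method = "convolution", sides = 1)
  v <- v[-(1:2)]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

sos_filter <- function(x, sos) {
  for (s in sos$sections) x <- biquad_filter(x, s$b, s$a)
  x * sos$gain
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) application of an order-4 Butterworth
#' band-pass, the 300 Hz - 1 kHz EMG acquisition band by default. Edge
#' transients are handled by odd-reflection padding. Zero-phase filtering
#' avoids biasing onset latencies, which differs from the causal filter of
#' the acquisition hardware.
#'
#' @param recording An `emg_recording` (see [simulate_emg()]) or a numeric
#'   vector (then `fs` must be given).
#' @param lo_hz,hi_hz Band edges (Hz); `hi_hz` must be below Nyquist.
#' @param fs Sampling rate when `recording` is a bare vector.
#' @param order Butterworth order (default 4).
#' @return The filtered recording (same type as the input).
#' @export
emg_bandpass <- function(recording, lo_hz = 300, hi_hz = 1000, fs = NULL,
                         order = 4L) {
  if (inherits(recording, "emg_recording")) {
    out <- recording
    out$volts <- emg_bandpass(recording$volts, lo_hz, hi_hz,
                              fs = recording$sampling_rate_hz, order = order)
    return(out)
  }
  x <- as.numeric(recording)
  if (is.null(fs)) abort("`fs` must be supplied for a bare numeric trace.")
  sos <- butter_bandpass_sos(lo_hz, hi_hz, fs, order)
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(6 * fs / lo_hz)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- sos_filter(xp, sos)
  y <- rev(sos_filter(rev(y), sos))
  y[(pad + 1):(pad + n)]
}

#' Moving-RMS envelope
#'
#' Centred moving root-mean-square of the rectified signal, the default
#' window being 5 ms.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_s RMS window (s), default 0.005.
#' @return Envelope, same length as `x`.
#' @export
emg_envelope <- function(x, fs, window_s = 0.005) {
  w <- max(1L, round(window_s * fs))
  cs <- cumsum(c(0, x^2))
  half <- w %/% 2
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' Detect ultrasound-evoked EMG responses
#'
#' Band-pass filters the recording, computes the moving-RMS envelope, and for
#' each stimulus searches for the first envelope crossing of
#' `baseline mean + k * baseline sd` strictly *after stimulus offset*: the
#' stimulus artifact makes within-pulse activity unquantifiable, so any
#' response starting during the pulse is discarded by construction. The
#' event ends when the envelope stays below threshold for at least
#' `release_s`. At most one event is called per stimulus (the first), so
#' raising `k` can only remove events. Latency is referenced to stimulus
#' *onset*, matching how evoked-response latencies are reported.
#'
#' @param recording An `emg_recording`.
#' @param k Threshold in baseline SDs above the baseline mean (default 3).
#' @param rms_window_s Envelope RMS window (s), default 0.005.
#' @param release_s Sub-threshold time that terminates an event (s),
#'   default 0.010.
#' @param min_duration_s Minimum time the envelope must remain above
#'   threshold for a crossing to count as an event onset (s, default 0.010
#'   = two RMS windows); transient noise blips shorter than this are not
#'   responses.
#' @param baseline_s Pre-stimulus baseline length required (s), default 1.
#' @param guard_s Blanking guard after stimulus offset (s, default 0.02):
#'   the zero-phase filter smears the sharp artifact edges into brief
#'   ringing just past cessation, which would otherwise be called as an
#'   event. Real responses at physiological latencies are unaffected.
#' @param lo_hz,hi_hz Band-pass edges (Hz).
#' @return Tibble of events: `stimulus`, `onset_s`, `latency_s`,
#'   `duration_s`, `peak_envelope`.
#' @export
detect_emg_events <- function(recording, k = 3, rms_window_s = 0.005,
                              release_s = 0.010, min_duration_s = 0.010,
                              baseline_s = 1, guard_s = 0.02,
                              lo_hz = 300, hi_hz = 1000) {
  stopifnot(inherits(recording, "emg_recording"))
  fs <- recording$sampling_rate_hz
  iv <- recording$stimulus_intervals_s
  if (!nrow(iv)) abort("Recording has no stimulus intervals.")
  if (iv[1, 1] < baseline_s) {
    abort(sprintf("Need at least %.2f s of pre-stimulus baseline.", baseline_s))
  }
  filt <- emg_bandpass(recording$volts, lo_hz, hi_hz, fs = fs)
  env <- emg_envelope(filt, fs, rms_window_s)
  tt <- (seq_along(env) - 1) / fs
  base <- env[tt < iv[1, 1] - rms_window_s]
  thr <- mean(base) + k * sd(base)
  release_n <- max(1L, round(release_s * fs))
  events <- purrr::map_dfr(seq_len(nrow(iv)), function(s) {
    t_on <- iv[s, 1]; t_off <- iv[s, 2]
    t_end <- if (s < nrow(iv)) iv[s + 1, 1] else max(tt) + 1 / fs
    # search strictly after stimulus cessation (plus the artifact guard)
    search <- which(tt > t_off + guard_s & tt < t_end)
    if (!length(search)) return(NULL)
    last <- search[length(search)]
    min_n <- max(1L, round(min_duration_s * fs))
    from <- search[1]
    repeat {
      cand <- which(env[from:last] > thr)
      if (!length(cand)) return(NULL)
      i0 <- from + cand[1] - 1L
      # event end: envelope below threshold for >= release_n samples
      j <- i0
      below_run <- 0L
      while (j < last && below_run < release_n) {
        j <- j + 1L
        below_run <- if (env[j] <= thr) below_run + 1L else 0L
      }
      end_idx <- j - below_run
      # onset persistence: discard blips shorter than the minimum duration
      if (sum(env[i0:end_idx] > thr) >= min_n) break
      if (j >= last) return(NULL)
      from <- j + 1L
    }
    tibble(stimulus = s, onset_s = tt[i0],
           latency_s = tt[i0] - t_on,
           duration_s = tt[end_idx] - tt[i0],
           peak_envelope = max(env[i0:end_idx]))
  })
  events
}

#' Summarise EMG responses
#'
#' @param events Tibble from [detect_emg_events()].
#' @param n_stimuli Total number of stimulations delivered.
#' @return A list with `rate` (responding stimuli / total) and `events`
#'   (the latency/duration table).
#' @export
summarize_emg <- function(events, n_stimuli) {
  check_number(n_stimuli, "n_stimuli", 1)
  n_resp <- if (is.null(events) || !nrow(events)) 0L
            else dplyr::n_distinct(events$stimulus)
  list(rate = n_resp / n_stimuli, events = events %||% tibble())
}
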