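#' Plan a synthetic EMG recording
#'
#' Describes a limb EMG acquisition around ultrasound pulses: band-limited
#' background noise, a rectangular stimulus-coincident artifact during each
#' pulse, and (optionally) an amplitude-modulated high-frequency burst at a
#' planted latency after pulse onset.
#'
#' @param sampling_rate_hz Sampling rate, default 40000 (must exceed 2 kHz so
#'   the 300-1000 Hz band of interest is resolvable).
#' @param duration_s Record length (s).
#' @param stimulus_intervals_s Two-column matrix or list of `c(on, off)`
#'   pairs (s), ordered and non-overlapping, within the record.
#' @param burst_latency_s Latency of the planted burst after pulse *onset*
#'   (s); must be non-negative. Use `NULL` for no planted responses.
#' @param burst_duration_s,burst_amplitude Planted burst envelope length (s)
#'   and peak amplitude (V).
#' @param burst_freq_hz Carrier frequency of the burst (Hz), inside the
#'   300-1000 Hz EMG band.
#' @param response_prob Probability that a given stimulus elicits a burst.
#' @param artifact_amplitude Amplitude (V) of the rectangular artifact during
#'   each pulse.
#' @param noise_sd Gaussian noise sd (V).
#' @param seed RNG seed.
#' @return An `emg_plan` list.
#' @export
emg_plan <- function(sampling_rate_hz = 40000, duration_s = 10,
                     stimulus_intervals_s = list(c(2, 2.1)),
                     burst_latency_s = 0.2, burst_duration_s = 0.15,
                     burst_amplitude = 1, burst_freq_hz = 600,
                     response_prob = 1, artifact_amplitude = 2,
                     noise_sd = 0.05, seed = 1L) {
  check_number(sampling_rate_hz, "sampling_rate_hz", 2000)
  check_number(duration_s, "duration_s", 1e-3)
  iv <- do.call(rbind, lapply(stimulus_intervals_s, function(x) {
    stopifnot(length(x) == 2, x[2] > x[1])
    x
  }))
  if (any(iv < 0) || any(iv > duration_s)) {
    abort("Stimulus intervals must lie within the record.")
  }
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
    abort("Stimulus intervals must be ordered and non-overlapping.")
  }
  if (!is.null(burst_latency_s)) {
    check_number(burst_latency_s, "burst_latency_s", 0)
    check_number(burst_duration_s, "burst_duration_s", 1e-6)
    if (any(iv[, 1] + burst_latency_s + burst_duration_s > duration_s)) {
      abort("Planted bursts must fall within the record.")
    }
  }
  check_fraction(response_prob, "response_prob")
  structure(list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 stimulus_intervals_s = iv,
                 burst_latency_s = burst_latency_s,
                 burst_duration_s = burst_duration_s,
                 burst_amplitude = burst_amplitude,
                 burst_freq_hz = burst_freq_hz,
                 response_prob = response_prob,
                 artifact_amplitude = artifact_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "emg_plan")
}

#' Simulate an EMG recording with planted response bursts
#'
#' @param plan An [emg_plan()].
#' @return A list with `recording` (an `emg_recording`: `sampling_rate_hz`,
#'   `volts`, `stimulus_intervals_s`) and `truth` (tibble of planted events:
#'   `stimulus`, `latency_s`, `onset_s`, `duration_s`, `amplitude`).
#' @export
simulate_emg <- function(plan) {
  stopifnot(inherits(plan, "emg_plan"))
  fs <- plan$sampling_rate_hz
  n <- round(plan$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  with_seed(plan$seed, {
    v <- rnorm(n, sd = plan$noise_sd)
    iv <- plan$stimulus_intervals_s
    for (k in seq_len(nrow(iv))) {
      inpulse <- tt >= iv[k, 1] & tt < iv[k, 2]
      v[inpulse] <- v[inpulse] + plan$artifact_amplitude
    }
    truth <- tibble(stimulus = integer(), latency_s = numeric(),
                    onset_s = numeric(), duration_s = numeric(),
                    amplitude = numeric())
    if (!is.null(plan$burst_latency_s)) {
      for (k in seq_len(nrow(iv))) {
        if (runif(1) > plan$response_prob) next
        t0 <- iv[k, 1] + plan$burst_latency_s
        inb <- tt >= t0 & tt < t0 + plan$burst_duration_s
        # Hann-windowed carrier: unit-peak envelope scaled by amplitude
        env <- sin(pi * (tt[inb] - t0) / plan$burst_duration_s)^2
        v[inb] <- v[inb] + plan$burst_amplitude * env *
          sin(2 * pi * plan$burst_freq_hz * (tt[inb] - t0))
        truth <- dplyr::bind_rows(truth, tibble(
          stimulus = k, latency_s = plan$burst_latency_s, onset_s = t0,
          duration_s = plan$burst_duration_s,
          amplitude = plan$burst_amplitude))
      }
    }
    rec <- structure(list(sampling_rate_hz = fs, volts = v,
                          stimulus_intervals_s = iv),
                     class = "emg_recording")
    list(recording = rec, truth = truth)
  })
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %.2f s @ %d Hz, %d stimuli\n",
              length(x$volts) / x$sampling_rate_hz, x$sampling_rate_hz,
              nrow(x$stimulus_intervals_s)))
  invisible(x)
}
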