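# Build a single-ROI dF/F-ready trace tibble at the acquisition frame rate.
trace_tbl <- function(values, fps = 16.6, roi = 1L) {
  tibble::tibble(roi = roi, frame = seq_along(values),
                 time_s = (seq_along(values) - 1) / fps, value = values)
}

test_that("dF/F of a constant positive trace is identically zero", {
  tr <- trace_tbl(rep(100, 200))
  dff <- compute_dff(tr, stimulus_onset_s = 7)
  expect_true(all(dff$dff == 0))
  expect_true(all(dff$f0 == 100))
  # arithmetic: baseline 100, excursion to 150 is dF/F = 0.5
  v <- rep(100, 200); v[150] <- 150
  dff2 <- compute_dff(trace_tbl(v), 7)
  expect_equal(dff2$dff[150], 0.5)
  # baseline placement: the 6 s immediately before the onset
  v3 <- c(rep(50, 17), rep(100, 183))  # first second differs
  dff3 <- compute_dff(trace_tbl(v3), 7)
  expect_equal(dff3$f0[1], 100)
  # errors: not enough pre-stimulus data; non-positive baseline
  expect_error(compute_dff(tr, 3), "baseline")
  expect_error(compute_dff(trace_tbl(rep(0, 200)), 7), "baseline")
})

test_that("responder calling applies the fixed 0.25 threshold inclusively", {
  mk <- function(peak) {
    v <- rep(100, 200)
    v[130:140] <- 100 * (1 + peak)
    compute_dff(trace_tbl(v), 7)
  }
  expect_true(call_response(mk(0.30), 7, window_s = 4)$responsive)
  expect_false(call_response(mk(0.20), 7, window_s = 4)$responsive)
  expect_true(call_response(mk(0.25), 7, window_s = 4)$responsive)  # ties pass
  flat <- call_response(mk(0), 7, window_s = 4)
  expect_false(flat$responsive)
  expect_equal(flat$peak_amplitude, 0)
  expect_error(call_response(mk(0.3), 7, window_s = 0), "window_s")
  expect_error(call_response(mk(0.3), 7, window_s = 1000), "window")
})

test_that("responsive count is non-increasing in the threshold", {
  set.seed(42)
  peaks <- runif(40, 0, 0.6)
  dffs <- purrr::map_dfr(seq_along(peaks), function(i) {
    v <- rep(100, 200); v[130] <- 100 * (1 + peaks[i])
    compute_dff(trace_tbl(v, roi = i), 7)
  })
  counts <- vapply(seq(0, 0.6, by = 0.05), function(th) {
    sum(call_response(dffs, 7, window_s = 4, threshold = th)$responsive)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("63% kinetics match analytic ramp and triangle crossings", {
  fps <- 16.6; onset <- 6
  tt <- seq(0, 20, by = 1 / fps)
  # linear ramp 0 -> peak over exactly 1 s from onset, then hold
  ramp <- pmin(pmax((tt - onset) / 1, 0), 1) * 0.5
  dff <- tibble::tibble(roi = 1L, frame = seq_along(tt), time_s = tt,
                        dff = ramp, f0 = 100)
  call <- call_response(dff, onset, window_s = 10)
  lw <- latency_and_width(dff, call, onset)
  expect_equal(lw$latency_s, 0.63, tolerance = 0.5 / fps)
  expect_true(lw$width_censored)  # plateau never decays below 63%

  # symmetric triangle of total duration 2 s: width = 2 * (1 - 0.63) s
  tri <- pmax(0, 1 - abs(tt - onset - 1)) * 0.5
  dff_t <- tibble::tibble(roi = 1L, frame = seq_along(tt), time_s = tt,
                          dff = tri, f0 = 100)
  call_t <- call_response(dff_t, onset, window_s = 10)
  lw_t <- latency_and_width(dff_t, call_t, onset)
  expect_equal(lw_t$width_s, 2 * (1 - 0.63), tolerance = 1 / fps)
  expect_false(lw_t$width_censored)

  # instantaneous step at onset: latency bounded by one frame period
  stp <- ifelse(tt >= onset, 0.5, 0)
  dff_s <- tibble::tibble(roi = 1L, frame = seq_along(tt), time_s = tt,
                          dff = stp, f0 = 100)
  lw_s <- latency_and_width(dff_s, call_response(dff_s, onset, 10), onset)
  expect_lte(lw_s$latency_s, 1 / fps)

  # invariants: latency <= time to peak; width >= 0
  expect_lte(lw_t$latency_s,
             call_t$peak_time_s - onset + 1e-9)
  expect_gte(lw_t$width_s, 0)
})

test_that("latency and width scale linearly under time-axis rescaling", {
  fps <- 50; onset <- 2
  for (scale in c(1, 2.5)) {
    tt <- seq(0, 20 * scale, by = 1 / fps)
    g <- transient_kernel((tt - onset * scale) / scale, 0.5, 2) * 0.5
    dff <- tibble::tibble(roi = 1L, frame = seq_along(tt), time_s = tt,
                          dff = g, f0 = 1)
    call <- call_response(dff, onset * scale, window_s = 15 * scale)
    lw <- latency_and_width(dff, call, onset * scale)
    if (scale == 1) {
      base <- lw
    } else {
      expect_equal(lw$latency_s / base$latency_s, scale, tolerance = 0.02)
      expect_equal(lw$width_s / base$width_s, scale, tolerance = 0.02)
    }
  }
})

test_that("percent responsive uses union semantics over three recordings", {
  mk_calls <- function(resp) tibble::tibble(roi = seq_along(resp),
                                            responsive = resp,
                                            threshold = 0.25)
  none <- replicate(3, mk_calls(c(FALSE, FALSE)), simplify = FALSE)
  expect_equal(percent_responsive(none), 0)
  # responsive only in recording 3 still counts exactly once
  only3 <- list(mk_calls(c(FALSE, FALSE)), mk_calls(c(FALSE, FALSE)),
                mk_calls(c(TRUE, FALSE)))
  expect_equal(percent_responsive(only3), 0.5)
  expect_equal(percent_responsive(only3, mode = "pooled"), 1 / 6)
  # mismatched ROI sets are an error
  bad <- list(mk_calls(c(TRUE, FALSE)),
              tibble::tibble(roi = 5:6, responsive = c(TRUE, FALSE),
                             threshold = 0.25))
  expect_error(percent_responsive(bad), "same ROI set")
})

test_that("union fraction over 3 recordings converges to 1-(1-q)^3", {
  q <- 0.3; n <- 4000
  set.seed(7)
  calls <- lapply(1:3, function(r) {
    tibble::tibble(roi = seq_len(n), responsive = runif(n) < q,
                   threshold = 0.25)
  })
  expected <- 1 - (1 - q)^3
  got <- percent_responsive(calls)
  expect_lt(abs(got - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("repeated stimulation profiles track planted per-cycle amplitudes", {
  onsets <- c(8, 18, 28)
  plan_eq <- movie_plan(n_cells = 3, duration_s = 40, height_px = 80,
                        width_px = 80, transfected_fraction = 1,
                        responder_fraction = 1, amplitude = 0.5,
                        stimulus_onsets_s = onsets, seed = 6)
  sim <- simulate_movie(plan_eq)
  rois <- segment_cells(sim$movie, seg_config(background_radius_px = 30))
  dff <- compute_dff(extract_traces(sim$movie, rois), onsets[1])
  prof <- repeated_stim_profile(dff, onsets)
  expect_equal(nrow(prof$cycle_peaks), 3)
  expect_lt(diff(range(prof$cycle_peaks$peak)), 0.01)
  # responses return toward baseline between pulses
  expect_true(all(prof$cycle_peaks$end_dff < 0.1 * prof$cycle_peaks$peak))

  # planted run-down: strictly decreasing per-cycle peaks
  plan_dec <- movie_plan(n_cells = 3, duration_s = 40, height_px = 80,
                         width_px = 80, transfected_fraction = 1,
                         responder_fraction = 1,
                         amplitude = c(0.6, 0.4, 0.25),
                         stimulus_onsets_s = onsets, seed = 6)
  sim2 <- simulate_movie(plan_dec)
  dff2 <- compute_dff(extract_traces(sim2$movie, rois), onsets[1])
  peaks2 <- repeated_stim_profile(dff2, onsets)$cycle_peaks$peak
  expect_true(all(diff(peaks2) < 0))

  # flat movie: flat profile
  plan_flat <- movie_plan(n_cells = 3, duration_s = 40, height_px = 80,
                          width_px = 80, transfected_fraction = 1,
                          responder_fraction = 0,
                          stimulus_onsets_s = onsets, seed = 6)
  dff3 <- compute_dff(extract_traces(simulate_movie(plan_flat)$movie, rois),
                      onsets[1])
  expect_lt(max(abs(repeated_stim_profile(dff3, onsets)$profile$mean_dff)),
            1e-9)
  expect_error(repeated_stim_profile(dff, onsets, window_s = 30), "closer")
})

test_that("mean agonist response equals the quadrature mean of the kernel", {
  fps <- 16.6; t_add <- 10
  tt <- seq(0, 110, by = 1 / fps)
  a <- 0.4
  vals <- a * transient_kernel(tt - t_add, 2, 30)
  dff <- tibble::tibble(roi = 1L, frame = seq_along(tt), time_s = tt,
                        dff = vals, f0 = 1)
  got <- mean_agonist_response(dff, t_add)$mean_dff
  oracle <- stats::integrate(function(x) a * transient_kernel(x, 2, 30),
                             0, 90, rel.tol = 1e-10)$value / 90
  expect_equal(got, oracle, tolerance = 1e-3)
  # trivial cases and the data-sufficiency error
  expect_equal(mean_agonist_response(
    tibble::tibble(roi = 1, frame = 1, time_s = seq(0, 100, 0.5),
                   dff = 0, f0 = 1), 5)$mean_dff, 0)
  expect_error(mean_agonist_response(dff, 100), "Insufficient")
})
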