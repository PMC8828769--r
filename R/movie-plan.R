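#' Plan a synthetic two-channel imaging movie
#'
#' Describes the stated world a synthetic acquisition emulates: a field of
#' disk-shaped cells imaged in two channels (a static transfection-marker
#' "segmentation" channel, dTomato-like, and a dynamic "activity" channel,
#' GCaMP6f-like) at 16.6 frames/s, with a subset of transfected cells planted
#' as responders carrying stimulus-locked rise/decay transients.
#'
#' Cells are hard disks convolved with a Gaussian point-spread function
#' (`psf_sigma_px`, default radius/3). Noise is Poisson shot noise (variance
#' `poisson_gain` x intensity; 0 disables) followed by additive Gaussian read
#' noise. Responder pixels are modulated multiplicatively,
#' \eqn{F(x,t) = S(x)\,(1 + A\,g(t - t_{on}))}, so every responder pixel has a
#' continuous-time peak dF/F of exactly the planted amplitude `A`.
#'
#' @param height_px,width_px Field size in pixels.
#' @param frame_rate_hz Acquisition rate (frames/s), default 16.6.
#' @param duration_s Recording length (s).
#' @param n_cells Number of planted cells.
#' @param transfected_fraction Fraction of cells carrying the marker, in
#'   `[0, 1]`.
#' @param responder_fraction Fraction of *transfected* cells planted as
#'   responders, in `[0, 1]`.
#' @param cell_radius_px,cell_radius_sd_px Mean and sd of cell radii (px).
#' @param amplitude Planted peak dF/F of responder transients; a scalar, or
#'   one value per stimulus (e.g. decaying amplitudes across repeats).
#' @param latency_s Delay from stimulus onset to transient onset (s).
#' @param rise_tau_s,decay_tau_s Transient kernel time constants (s), see
#'   [transient_kernel()].
#' @param f0 Baseline cell fluorescence (a.u.).
#' @param background Background fluorescence added everywhere (a.u.).
#' @param poisson_gain Shot-noise gain: pixel variance `poisson_gain * I`.
#'   `0` disables shot noise.
#' @param read_sd Additive Gaussian read-noise sd (a.u.).
#' @param stimulus_onsets_s Stimulus onset times (s), strictly inside the
#'   recording; defaults to 8 s (or mid-recording for movies shorter than
#'   that).
#' @param min_separation Minimum centre distance between two cells, as a
#'   multiple of the sum of their radii (1 = exactly touching). The default
#'   1.5 keeps each responder's modulated PSF footprint (disk + 2 sigma)
#'   clear of neighbouring ROIs, so recovered amplitudes are uncontaminated;
#'   lower it deliberately to generate touching cells for watershed tests.
#' @param seed RNG seed; fixes the generated movie bit-for-bit.
#' @return A `movie_plan` list, validated.
#' @seealso [simulate_movie()]
#' @export
movie_plan <- function(height_px = 128, width_px = 128,
                       frame_rate_hz = 16.6, duration_s = 20,
                       n_cells = 10,
                       transfected_fraction = 0.5,
                       responder_fraction = 0.5,
                       cell_radius_px = 6, cell_radius_sd_px = 0.5,
                       amplitude = 0.5, latency_s = 0.1,
                       rise_tau_s = 0.5, decay_tau_s = 2,
                       f0 = 100, background = 10,
                       poisson_gain = 0, read_sd = 0,
                       stimulus_onsets_s = NULL,
                       min_separation = 1.5,
                       seed = 1L) {
  check_number(height_px, "height_px", 8); check_number(width_px, "width_px", 8)
  check_number(frame_rate_hz, "frame_rate_hz", 1e-6)
  check_number(duration_s, "duration_s", 1e-6)
  check_number(n_cells, "n_cells", 0)
  check_fraction(transfected_fraction, "transfected_fraction")
  check_fraction(responder_fraction, "responder_fraction")
  check_number(cell_radius_px, "cell_radius_px", 1)
  check_number(cell_radius_sd_px, "cell_radius_sd_px", 0)
  if (!is.numeric(amplitude) || !length(amplitude) || any(amplitude < 0)) {
    abort("`amplitude` must be non-negative (scalar or one value per stimulus).")
  }
  check_number(latency_s, "latency_s", 0)
  check_number(rise_tau_s, "rise_tau_s", 1e-12)
  check_number(decay_tau_s, "decay_tau_s", 1e-12)
  if (decay_tau_s <= rise_tau_s) abort("`decay_tau_s` must exceed `rise_tau_s`.")
  check_number(f0, "f0", 1e-12)
  check_number(background, "background", 0)
  check_number(poisson_gain, "poisson_gain", 0)
  check_number(read_sd, "read_sd", 0)
  check_number(min_separation, "min_separation", 0.5)
  stimulus_onsets_s <- stimulus_onsets_s %||% min(8, duration_s / 2)
  if (length(stimulus_onsets_s) < 1 || any(stimulus_onsets_s < 0) ||
      any(stimulus_onsets_s >= duration_s)) {
    abort("`stimulus_onsets_s` must lie within [0, duration_s).")
  }
  structure(
    list(height_px = height_px, width_px = width_px,
         frame_rate_hz = frame_rate_hz, duration_s = duration_s,
         n_cells = as.integer(n_cells),
         transfected_fraction = transfected_fraction,
         responder_fraction = responder_fraction,
         cell_radius_px = cell_radius_px,
         cell_radius_sd_px = cell_radius_sd_px,
         amplitude = amplitude, latency_s = latency_s,
         rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
         f0 = f0, background = background,
         poisson_gain = poisson_gain, read_sd = read_sd,
         stimulus_onsets_s = sort(as.numeric(stimulus_onsets_s)),
         min_separation = min_separation,
         seed = as.integer(seed)),
    class = "movie_plan")
}

#' @export
print.movie_plan <- function(x, ...) {
  cat(sprintf(
    "<movie_plan> %dx%d px, %.1f s @ %.1f fps, %d cells (%.0f%% transfected, %.0f%% responders), A=%.2f\n",
    x$height_px, x$width_px, x$duration_s, x$frame_rate_hz, x$n_cells,
    100 * x$transfected_fraction, 100 * x$responder_fraction, x$amplitude))
  invisible(x)
}
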