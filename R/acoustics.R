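#' Ultrasound focal and attenuation arithmetic
#'
#' Small calculators for the physical quantities that set the spatial scale
#' and tissue penetration of an ultrasound stimulus in brain tissue:
#' wavelength \eqn{\lambda = c/f} with c the speed of sound in brain tissue
#' (1500 m/s), the diffraction-limited focal dimension \eqn{\lambda/2},
#' tissue attenuation at 0.8 dB cm^-1 MHz^-1, and the mechanical index
#' (cavitation-risk proxy) \eqn{MI = PNP/\sqrt{f_{MHz}}}.
#'
#' @param frequency_hz Ultrasound frequency (Hz), > 0.
#' @param sound_speed_m_s Speed of sound (m/s), default 1500 (brain tissue).
#' @return `us_wavelength()`: wavelength in metres.
#' @examples
#' us_wavelength(7e6) / 2 * 1e6  # ~107 micrometres at 7 MHz
#' us_attenuation(7e6, depth_cm = 0.5)
#' mechanical_index(2.5, 7)
#' @export
us_wavelength <- function(frequency_hz, sound_speed_m_s = 1500) {
  if (any(frequency_hz <= 0)) abort("`frequency_hz` must be positive.")
  check_number(sound_speed_m_s, "sound_speed_m_s", 1e-9)
  sound_speed_m_s / frequency_hz
}

#' @rdname us_wavelength
#' @return `us_focal_dimension()`: tibble with the diffraction-limited focal
#'   dimension `focal_dim_m` (= lambda/2) and two candidate focal volumes,
#'   `focal_volume_halflambda_m3` (= (lambda/2)^3) and
#'   `focal_volume_lambda_m3` (= lambda^3); both volume conventions appear
#'   in the literature, so both are reported.
#' @export
us_focal_dimension <- function(frequency_hz, sound_speed_m_s = 1500) {
  lam <- us_wavelength(frequency_hz, sound_speed_m_s)
  tibble(frequency_hz = frequency_hz, wavelength_m = lam,
         focal_dim_m = lam / 2,
         focal_volume_halflambda_m3 = (lam / 2)^3,
         focal_volume_lambda_m3 = lam^3)
}

#' @rdname us_wavelength
#' @param depth_cm Tissue depth (cm), >= 0.
#' @param coeff_db_cm_mhz Attenuation coefficient, default 0.8 dB/(cm MHz).
#' @return `us_attenuation()`: tibble with `attenuation_db`
#'   (= coeff x f_MHz x depth), and the transmitted fraction under both the
#'   pressure (`10^(-dB/20)`) and intensity (`10^(-dB/10)`) conventions.
#' @export
us_attenuation <- function(frequency_hz, depth_cm,
                           coeff_db_cm_mhz = 0.8) {
  if (any(frequency_hz <= 0)) abort("`frequency_hz` must be positive.")
  if (any(depth_cm < 0)) abort("`depth_cm` must be non-negative.")
  check_number(coeff_db_cm_mhz, "coeff_db_cm_mhz", 0)
  db <- coeff_db_cm_mhz * (frequency_hz / 1e6) * depth_cm
  tibble(frequency_hz = frequency_hz, depth_cm = depth_cm,
         attenuation_db = db,
         pressure_fraction = 10^(-db / 20),
         intensity_fraction = 10^(-db / 10))
}

#' @rdname us_wavelength
#' @param pnp_mpa Peak negative pressure (MPa), > 0.
#' @param f_mhz Frequency (MHz), > 0.
#' @return `mechanical_index()`: the mechanical index (dimensionless).
#' @export
mechanical_index <- function(pnp_mpa, f_mhz) {
  if (any(pnp_mpa <= 0) || any(f_mhz <= 0)) {
    abort("Pressure and frequency must be positive.")
  }
  pnp_mpa / sqrt(f_mhz)
}

#' Acoustic report for one stimulus configuration
#'
#' Convenience wrapper combining wavelength, focal dimension/volumes,
#' attenuation at a depth, and (if a pressure is given) the mechanical
#' index into one row.
#'
#' @param frequency_hz Frequency (Hz).
#' @param depth_cm Depth for the attenuation estimate (cm), default 0.5.
#' @param pnp_mpa Optional peak negative pressure (MPa).
#' @param sound_speed_m_s,coeff_db_cm_mhz Medium constants.
#' @return One-row tibble with all derived quantities.
#' @export
acoustic_report <- function(frequency_hz, depth_cm = 0.5, pnp_mpa = NULL,
                            sound_speed_m_s = 1500, coeff_db_cm_mhz = 0.8) {
  foc <- us_focal_dimension(frequency_hz, sound_speed_m_s)
  att <- us_attenuation(frequency_hz, depth_cm, coeff_db_cm_mhz)
  out <- dplyr::bind_cols(foc, att[, -1])
  out$mechanical_index <- if (is.null(pnp_mpa)) NA_real_ else
    mechanical_index(pnp_mpa, frequency_hz / 1e6)
  out
}
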