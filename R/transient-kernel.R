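#' Normalised calcium transient kernel
#'
#' Difference-of-exponentials kernel used to plant GCaMP-like transients in
#' synthetic movies: \eqn{g(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}} for
#' \eqn{t \ge 0} (zero before onset), scaled so its maximum is exactly 1. A
#' planted transient with peak amplitude `A` therefore has a continuous-time
#' peak dF/F of exactly `A`, which downstream detectors are benchmarked
#' against.
#'
#' @param t Numeric vector of times (s) relative to transient onset.
#' @param rise_tau_s Rise time constant (s), must be positive and smaller than
#'   `decay_tau_s`.
#' @param decay_tau_s Decay time constant (s).
#' @return `transient_kernel()`: kernel values in `[0, 1]`, zero for `t < 0`.
#' @examples
#' tt <- seq(0, 10, by = 0.06)
#' g <- transient_kernel(tt, 0.5, 2)
#' max(g) # approaches 1 at the analytic peak time
#' transient_peak_time(0.5, 2)
#' @export
transient_kernel <- function(t, rise_tau_s, decay_tau_s) {
  check_number(rise_tau_s, "rise_tau_s", lower = 1e-12)
  check_number(decay_tau_s, "decay_tau_s", lower = 1e-12)
  if (decay_tau_s <= rise_tau_s) {
    abort("`decay_tau_s` must exceed `rise_tau_s` for a rise/decay transient.")
  }
  tp <- transient_peak_time(rise_tau_s, decay_tau_s)
  gmax <- exp(-tp / decay_tau_s) - exp(-tp / rise_tau_s)
  out <- (exp(-t / decay_tau_s) - exp(-t / rise_tau_s)) / gmax
  out[t < 0] <- 0
  out
}

#' @rdname transient_kernel
#' @return `transient_peak_time()`: the time (s) after onset at which the
#'   kernel attains its maximum, \eqn{t^* = \frac{\tau_r \tau_d}{\tau_d -
#'   \tau_r} \log(\tau_d/\tau_r)}.
#' @export
transient_peak_time <- function(rise_tau_s, decay_tau_s) {
  rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s) *
    log(decay_tau_s / rise_tau_s)
}
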