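#' Simulate a pressure dose-response cohort
#'
#' Each cell's probability of responding to ultrasound follows a Hill law in
#' peak pressure, \eqn{p(P) = p_{max} P^h / (P^h + EC_{50}^h)}; cells are
#' sampled as independent Bernoulli trials and labelled by coverslip.
#'
#' @param pressures_mpa Positive pressures (MPa), one cohort level each.
#' @param pmax Plateau response probability, in `[0, 1]`.
#' @param ec50_mpa Half-maximal pressure (MPa).
#' @param hill Hill coefficient (> 0).
#' @param n_cells_per_coverslip,n_coverslips Cohort size per pressure level.
#' @param seed RNG seed.
#' @return Tibble: `pressure_mpa`, `coverslip`, `cell`, `p_true`, `response`.
#' @export
simulate_dose_cohort <- function(pressures_mpa, pmax = 0.8, ec50_mpa = 0.5,
                                 hill = 3, n_cells_per_coverslip = 50,
                                 n_coverslips = 3, seed = 1L) {
  if (!length(pressures_mpa)) abort("`pressures_mpa` must be non-empty.")
  if (any(pressures_mpa <= 0)) abort("Pressures must be positive.")
  check_fraction(pmax, "pmax")
  check_number(ec50_mpa, "ec50_mpa", 1e-12)
  check_number(hill, "hill", 1e-12)
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      pressure_mpa = pressures_mpa,
      coverslip = seq_len(n_coverslips),
      cell = seq_len(n_cells_per_coverslip))
    grid |>
      dplyr::mutate(
        p_true = hill_response(.data$pressure_mpa, pmax, ec50_mpa, hill),
        response = rbinom(dplyr::n(), 1L, .data$p_true))
  })
}

#' Hill dose-response law
#'
#' @param pressure_mpa Pressure (MPa).
#' @param pmax,ec50_mpa,hill Hill parameters (plateau, half-max, coefficient).
#' @return Response probability.
#' @export
hill_response <- function(pressure_mpa, pmax, ec50_mpa, hill) {
  pmax * pressure_mpa^hill / (pressure_mpa^hill + ec50_mpa^hill)
}

#' Simulate a clone-screen Bernoulli dataset
#'
#' Generates cell-level 0/1 responses under the random-intercept logistic
#' model the screen statistic assumes: logit P(response) = clone effect +
#' cell intercept, with cell intercepts drawn N(0, `sigma_cell`^2), and
#' `n_recordings` repeated observations per cell.
#'
#' @param clone_logodds Named numeric vector of clone fixed effects on the
#'   log-odds scale (the first entry is conventionally the control clone).
#' @param n_cells Cells per clone.
#' @param n_recordings Repeated recordings per cell (default 3).
#' @param sigma_cell SD of the per-cell random intercept.
#' @param seed RNG seed.
#' @return Tibble: `clone` (factor, levels in the given order), `coverslip`,
#'   `cell` (unique across clones), `recording`, `response`.
#' @export
simulate_screen <- function(clone_logodds, n_cells = 200, n_recordings = 3,
                            sigma_cell = 1, seed = 1L) {
  if (is.null(names(clone_logodds))) {
    names(clone_logodds) <- paste0("clone", seq_along(clone_logodds))
  }
  check_number(sigma_cell, "sigma_cell", 0)
  with_seed(seed, {
    purrr::imap_dfr(clone_logodds, function(beta, cl) {
      u <- rnorm(n_cells, 0, sigma_cell)
      tidyr::expand_grid(cell_local = seq_len(n_cells),
                         recording = seq_len(n_recordings)) |>
        dplyr::mutate(
          clone = cl,
          p = plogis(beta + u[.data$cell_local]),
          response = rbinom(dplyr::n(), 1L, .data$p))
    }) |>
      dplyr::mutate(
        clone = factor(.data$clone, levels = names(clone_logodds)),
        cell = paste(.data$clone, .data$cell_local, sep = "_"),
        coverslip = paste(.data$clone, 1 + (.data$cell_local - 1) %/% 50,
                          sep = "_cs")) |>
      dplyr::select("clone", "coverslip", "cell", "recording", "response")
  })
}
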