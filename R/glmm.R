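#' Fit the screen's Bernoulli random-intercept model
#'
#' Fits logit P(response) = clone (fixed factor) + cell (Gaussian random
#' intercept) to cell-level 0/1 responses, maximising the marginal
#' likelihood by adaptive Gauss-Hermite quadrature (25 nodes by default).
#' This is the screen statistic used to compare ultrasound-responsiveness
#' between channel clones while respecting repeated recordings of the same
#' cell.
#'
#' With `collapse_random = TRUE` the random intercept is dropped
#' (sigma^2 fixed at 0) and the model collapses to an ordinary logistic
#' regression — useful when every cell contributes one observation.
#'
#' @param data Tibble with columns `clone` (factor; the first level is the
#'   reference, conventionally the control/dTomato-only clone), `cell`,
#'   `response` (0/1), and optionally `recording`/`coverslip`.
#' @param reference Optional clone label to use as the reference level.
#' @param nagq Number of adaptive Gauss-Hermite quadrature nodes
#'   (default 25).
#' @param collapse_random Force sigma^2 = 0 (plain logistic fit).
#' @return A `screen_glmm` object: list with `coef` (named fixed effects,
#'   log-odds, reference-coded), `vcov`, `sigma_cell` (random-intercept SD),
#'   `loglik`, `converged`, `nagq`, `model` (the underlying fit), `clones`.
#' @examples
#' dat <- simulate_screen(c(control = -2, hsTRPA1 = -0.5),
#'                        n_cells = 40, seed = 3)
#' fit <- fit_response_glmm(dat, nagq = 9)
#' tidy(fit)
#' @export
fit_response_glmm <- function(data, reference = NULL, nagq = 25,
                              collapse_random = FALSE) {
  stopifnot(all(c("clone", "cell", "response") %in% names(data)))
  data <- dplyr::mutate(data, clone = factor(.data$clone))
  if (nlevels(data$clone) < 2) abort("Need at least two clones.")
  if (!is.null(reference)) {
    data$clone <- stats::relevel(data$clone, ref = reference)
  }
  if (!all(data$response %in% c(0, 1))) abort("`response` must be 0/1.")
  if (collapse_random) {
    fit <- stats::glm(response ~ clone, family = stats::binomial(), data = data)
    out <- list(coef = coef(fit), vcov = vcov(fit), sigma_cell = 0,
                loglik = as.numeric(logLik(fit)),
                converged = fit$converged, nagq = NA_integer_,
                model = fit, clones = levels(data$clone))
    return(structure(out, class = "screen_glmm"))
  }
  check_number(nagq, "nagq", 1)
  fit <- lme4::glmer(response ~ clone + (1 | cell), data = data,
                     family = stats::binomial(), nAGQ = as.integer(nagq))
  conv <- length(fit@optinfo$conv$lme4) == 0 &&
    isTRUE(fit@optinfo$conv$opt == 0)
  out <- list(coef = lme4::fixef(fit),
              vcov = as.matrix(vcov(fit)),
              sigma_cell = sqrt(unlist(lme4::VarCorr(fit))[["cell"]]),
              loglik = as.numeric(logLik(fit)),
              converged = conv, nagq = as.integer(nagq),
              model = fit, clones = levels(data$clone))
  structure(out, class = "screen_glmm")
}

#' @export
print.screen_glmm <- function(x, ...) {
  cat(sprintf("<screen_glmm> %d clones, sigma_cell = %.3f, logLik = %.2f%s\n",
              length(x$clones), x$sigma_cell, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  print(x$coef)
  invisible(x)
}

#' @rdname fit_response_glmm
#' @param x,object A `screen_glmm` fit.
#' @param ... Unused.
#' @export
tidy.screen_glmm <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std.error = unname(se),
         statistic = unname(x$coef / se),
         p.value = 2 * pnorm(-abs(unname(x$coef / se))))
}

#' @rdname fit_response_glmm
#' @export
glance.screen_glmm <- function(x, ...) {
  tibble(sigma_cell = x$sigma_cell, logLik = x$loglik,
         nagq = x$nagq, converged = x$converged,
         n_clones = length(x$clones))
}

#' Tukey-adjusted pairwise odds ratios between clones
#'
#' Builds every pairwise contrast of the clone fixed effects, reports the
#' odds ratio `exp(contrast)`, and controls the family-wise error with the
#' single-step (Tukey-style) adjustment: p-values and confidence limits use
#' the equicoordinate quantiles of the contrasts' joint normal distribution
#' (computed with a deterministic quasi-Monte-Carlo integration seed). With
#' only two clones the family has one member and the adjusted p equals the
#' unadjusted p.
#'
#' @param fit A converged `screen_glmm` from [fit_response_glmm()].
#' @param conf_level Family-wise confidence level, default 0.95.
#' @return Tibble: `contrast`, `log_or`, `se`, `odds_ratio`, `statistic`,
#'   `p.value` (unadjusted), `adj.p.value`, `conf.low`, `conf.high`
#'   (adjusted, on the OR scale).
#' @export
pairwise_odds_ratios <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "screen_glmm"))
  if (!fit$converged) abort("Refusing to compute contrasts from a non-converged fit.")
  k <- length(fit$clones)
  # clone means on the log-odds scale: reference-coded design
  cf <- c(0, fit$coef[-1])            # effect of each clone vs reference
  v <- matrix(0, k, k)
  v[-1, -1] <- fit$vcov[-1, -1, drop = FALSE]
  pairs <- utils::combn(k, 2)
  cmat <- matrix(0, ncol(pairs), k)
  labs <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    cmat[j, b] <- 1; cmat[j, a] <- -1
    labs[j] <- paste(fit$clones[b], fit$clones[a], sep = " / ")
  }
  est <- as.numeric(cmat %*% cf)
  cv <- cmat %*% v %*% t(cmat)
  se <- sqrt(diag(cv))
  z <- est / se
  corr <- cv / (se %o% se)
  m <- length(z)
  p_unadj <- 2 * pnorm(-abs(z))
  if (m == 1L) {
    p_adj <- p_unadj
    q <- qnorm(1 - (1 - conf_level) / 2)
  } else {
    alg <- mvtnorm::GenzBretz(abseps = 1e-6)
    # quasi-Monte-Carlo integration under a fixed private RNG stream
    p_adj <- with_seed(1L, vapply(abs(z), function(zz) {
      1 - mvtnorm::pmvnorm(lower = rep(-zz, m), upper = rep(zz, m),
                           corr = corr, algorithm = alg)[1]
    }, numeric(1)))
    p_adj <- pmin(1, pmax(p_adj, p_unadj))  # adjusted never below unadjusted
    q <- with_seed(1L, mvtnorm::qmvnorm(conf_level, tail = "both.tails",
                                        corr = corr)$quantile)
  }
  tibble(contrast = labs, log_or = est, se = se,
         odds_ratio = exp(est), statistic = z,
         p.value = p_unadj, adj.p.value = p_adj,
         conf.low = exp(est - q * se), conf.high = exp(est + q * se))
}

#' Dose-response aggregation with exact binomial intervals
#'
#' Groups cell-level responses by a dose variable (pressure or pulse
#' duration) and reports the responsive fraction with exact
#' Clopper-Pearson 95% intervals per level.
#'
#' @param data Tibble with a `response` (0/1) column.
#' @param dose Column (tidy-eval) holding the dose level, e.g.
#'   `pressure_mpa`.
#' @param conf_level Interval level, default 0.95.
#' @return Tibble: dose level, `n`, `n_responsive`, `fraction`, `conf.low`,
#'   `conf.high`.
#' @export
dose_response_table <- function(data, dose, conf_level = 0.95) {
  stopifnot("response" %in% names(data))
  if (!nrow(data)) abort("Empty dose-response data.")
  data |>
    dplyr::group_by({{ dose }}) |>
    dplyr::summarise(n = dplyr::n(),
                     n_responsive = sum(.data$response),
                     .groups = "drop") |>
    dplyr::mutate(
      fraction = .data$n_responsive / .data$n,
      conf.low = stats::qbeta((1 - conf_level) / 2, .data$n_responsive,
                              .data$n - .data$n_responsive + 1),
      conf.high = stats::qbeta(1 - (1 - conf_level) / 2,
                               .data$n_responsive + 1,
                               .data$n - .data$n_responsive)) |>
    dplyr::mutate(
      conf.low = ifelse(.data$n_responsive == 0, 0, .data$conf.low),
      conf.high = ifelse(.data$n_responsive == .data$n, 1, .data$conf.high))
}
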