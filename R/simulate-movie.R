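#' Simulate a ground-truthed two-channel imaging movie
#'
#' Renders the acquisition described by a [movie_plan()]: disk cells blurred
#' by a Gaussian PSF (sigma = radius/3), a static marker channel for
#' transfected cells, and an activity channel in which responder pixels are
#' multiplicatively modulated by a stimulus-locked [transient_kernel()].
#' Poisson shot noise and Gaussian read noise are applied per frame. The same
#' plan (including its seed) reproduces the movie bit-for-bit.
#'
#' Every planted object is returned in the ground-truth table, which is the
#' oracle downstream segmentation/kinetics benchmarks compare against.
#'
#' @param plan A [movie_plan()].
#' @return A list with elements `movie` (an [imaging_movie()]) and `truth`
#'   (a tibble with one row per planted cell: `cell`, `row`, `col`,
#'   `radius_px`, `transfected`, `responder`, `amplitude`, `latency_s`,
#'   `rise_tau_s`, `decay_tau_s`).
#' @examples
#' sim <- simulate_movie(movie_plan(n_cells = 3, duration_s = 12, seed = 7))
#' sim$movie
#' sim$truth
#' @export
simulate_movie <- function(plan) {
  stopifnot(inherits(plan, "movie_plan"))
  h <- plan$height_px; w <- plan$width_px
  nt <- max(1L, round(plan$duration_s * plan$frame_rate_hz))
  with_seed(plan$seed, {
    cells <- place_cells(plan)
    n <- nrow(cells)
    # static patterns (pre-noise)
    psf_sigma <- plan$cell_radius_px / 3
    seg_static <- matrix(plan$background, h, w)
    act_static <- matrix(plan$background, h, w)
    pix_sets <- vector("list", n)
    if (n > 0) {
      seg_disks <- matrix(0, h, w)
      act_disks <- matrix(0, h, w)
      for (i in seq_len(n)) {
        px <- cell_pixels(cells$row[i], cells$col[i], cells$radius_px[i], h, w)
        pix_sets[[i]] <- px
        act_disks[px] <- act_disks[px] + plan$f0
        if (cells$transfected[i]) seg_disks[px] <- seg_disks[px] + plan$f0
      }
      seg_static <- seg_static + gaussian_blur(seg_disks, psf_sigma)
      act_static <- act_static + gaussian_blur(act_disks, psf_sigma)
    }
    # time-dependent modulation of responder disk pixels
    tt <- (seq_len(nt) - 1) / plan$frame_rate_hz
    amps <- rep_len(plan$amplitude, length(plan$stimulus_onsets_s))
    gmod <- rep(0, nt)
    for (k in seq_along(plan$stimulus_onsets_s)) {
      gmod <- gmod + amps[k] *
        transient_kernel(tt - plan$stimulus_onsets_s[k] - plan$latency_s,
                         plan$rise_tau_s, plan$decay_tau_s)
    }
    act_mat <- matrix(act_static, h * w, nt)
    if (n > 0) {
      # Modulate out to the PSF support (disk + 2 sigma) so that any ROI
      # inside a responder's footprint measures a peak dF/F of exactly A:
      # every modulated pixel obeys F(t) = F0_pixel * (1 + A g(t)). The
      # default min_separation keeps these footprints clear of neighbouring
      # cells' ROIs.
      for (i in which(cells$responder)) {
        px <- cell_pixels(cells$row[i], cells$col[i],
                          cells$radius_px[i] + 2 * psf_sigma, h, w)
        act_mat[px, ] <- act_mat[px, ] * rep(1 + gmod, each = length(px))
      }
    }
    seg_mat <- matrix(seg_static, h * w, nt)
    if (plan$poisson_gain > 0) {
      g <- plan$poisson_gain
      act_mat[] <- rpois(length(act_mat), act_mat / g) * g
      seg_mat[] <- rpois(length(seg_mat), seg_mat / g) * g
    }
    if (plan$read_sd > 0) {
      act_mat[] <- act_mat + rnorm(length(act_mat), sd = plan$read_sd)
      seg_mat[] <- seg_mat + rnorm(length(seg_mat), sd = plan$read_sd)
    }
    movie <- imaging_movie(
      segmentation = array(seg_mat, dim = c(h, w, nt)),
      activity = array(act_mat, dim = c(h, w, nt)),
      frame_rate_hz = plan$frame_rate_hz,
      stimulus_onsets_s = plan$stimulus_onsets_s)
    truth <- if (n > 0) {
      tibble(cell = seq_len(n),
             row = cells$row, col = cells$col,
             radius_px = cells$radius_px,
             transfected = cells$transfected,
             responder = cells$responder,
             amplitude = ifelse(cells$responder, amps[1], 0),
             latency_s = ifelse(cells$responder, plan$latency_s, NA_real_),
             rise_tau_s = ifelse(cells$responder, plan$rise_tau_s, NA_real_),
             decay_tau_s = ifelse(cells$responder, plan$decay_tau_s, NA_real_))
    } else {
      tibble(cell = integer(), row = numeric(), col = numeric(),
             radius_px = numeric(), transfected = logical(),
             responder = logical(), amplitude = numeric(),
             latency_s = numeric(), rise_tau_s = numeric(),
             decay_tau_s = numeric())
    }
    list(movie = movie, truth = truth)
  })
}

# Rejection-sample cell centres respecting the minimum-separation rule and a
# hard packing limit; assign transfection/responder flags.
place_cells <- function(plan) {
  n <- plan$n_cells
  h <- plan$height_px; w <- plan$width_px
  if (n == 0L) {
    return(tibble(row = numeric(), col = numeric(), radius_px = numeric(),
                  transfected = logical(), responder = logical()))
  }
  radii <- pmax(1.5, rnorm(n, plan$cell_radius_px, plan$cell_radius_sd_px))
  margin <- radii + plan$cell_radius_px  # keep cell + PSF tail inside field
  packing <- sum(pi * (plan$min_separation * radii)^2) / (h * w)
  if (packing > 0.5) {
    abort(sprintf(
      "Cannot place %d cells: packing fraction %.2f exceeds the limit 0.5.",
      n, packing))
  }
  rows <- numeric(n); cols <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      r <- runif(1, margin[i], h - margin[i])
      c <- runif(1, margin[i], w - margin[i])
      if (i == 1L) { ok <- TRUE } else {
        j <- seq_len(i - 1L)
        ok <- all((r - rows[j])^2 + (c - cols[j])^2 >=
                    (plan$min_separation * (radii[i] + radii[j]))^2)
      }
      if (ok) { rows[i] <- r; cols[i] <- c; break }
    }
    if (!ok) {
      abort(sprintf(
        "Cannot place %d cells without violating the packing limit (min separation %.2f x summed radii / 2).",
        n, plan$min_separation))
    }
  }
  transfected <- runif(n) < plan$transfected_fraction
  responder <- transfected & (runif(n) < plan$responder_fraction)
  tibble(row = round(rows, 1), col = round(cols, 1), radius_px = round(radii, 2),
         transfected = transfected, responder = responder)
}
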