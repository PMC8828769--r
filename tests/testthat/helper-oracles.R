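# Independent oracles used to cross-check the package's implementations.
# Each oracle deliberately uses a different computational route than the
# code path it validates.

# Plain logistic regression by hand-rolled iteratively reweighted least
# squares (checks the sigma^2 = 0 collapse of the screen GLMM).
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) return(as.numeric(beta_new))
    beta <- as.numeric(beta_new)
  }
  beta
}

# Marginal log-likelihood of the Bernoulli random-intercept model by dense
# trapezoid integration over the random effect (checks the adaptive
# Gauss-Hermite likelihood reported by the fit).
grid_marginal_loglik <- function(data, beta, sigma, half_width = 10,
                                 n_grid = 8001) {
  X <- stats::model.matrix(~clone, data = data)
  eta_fix <- as.numeric(X %*% beta)
  if (sigma < 1e-6) {  # degenerate random effect: no integration needed
    p <- stats::plogis(eta_fix)
    return(sum(log(ifelse(data$response == 1, p, 1 - p))))
  }
  u <- seq(-half_width * max(sigma, 0.1), half_width * max(sigma, 0.1),
           length.out = n_grid)
  du <- u[2] - u[1]
  phi <- stats::dnorm(u, 0, sigma)
  ll <- 0
  for (cl in unique(data$cell)) {
    i <- which(data$cell == cl)
    # P(y_i | u) on the grid: outer over observations x grid
    eta <- outer(eta_fix[i], u, `+`)
    p <- stats::plogis(eta)
    obs <- p
    zero <- data$response[i] == 0
    obs[zero, ] <- 1 - p[zero, , drop = FALSE]
    lik_given_u <- exp(colSums(log(obs)))
    ll <- ll + log(sum(lik_given_u * phi) * du)
  }
  ll
}

# Brute-force CRAC/CARC scan: explicit regular expressions for every
# (gap1, gap2) combination, tested at every start position.
brute_motif_scan <- function(seq, pattern = "CRAC", strict = FALSE) {
  sets <- if (pattern == "CRAC") {
    list(a1 = "[LV]", ce = "Y", a2 = "[RK]")
  } else {
    list(a1 = "[RK]", ce = "[YF]", a2 = "[LV]")
  }
  spacer <- if (strict) "[AVLIPFMWGC]" else "[A-Z]"
  n <- nchar(seq)
  hits <- list()
  for (g1 in 1:5) {
    for (g2 in 1:5) {
      span <- 3 + g1 + g2
      if (span > n) next
      rx <- paste0("^", sets$a1, spacer, "{", g1, "}", sets$ce,
                   spacer, "{", g2, "}", sets$a2, "$")
      starts <- seq_len(n - span + 1)
      frags <- substring(seq, starts, starts + span - 1)
      ok <- grepl(rx, frags)
      if (any(ok)) {
        hits[[length(hits) + 1]] <- data.frame(
          pattern = pattern, start = starts[ok], end = starts[ok] + span - 1,
          central = starts[ok] + 1 + g1, match = frags[ok])
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(pattern = character(), start = integer(), end = integer(),
               central = integer(), match = character())
  out[order(out$pattern, out$start, out$end), , drop = FALSE]
}

# Per-column consensus/identity by explicit counting loops.
brute_consensus <- function(seqs, threshold, count_gaps = TRUE) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  out <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (!count_gaps) col <- col[col != "-"]
    if (!length(col)) { out[j] <- "-"; next }
    best <- ""; best_n <- -1; tie <- FALSE
    for (sym in unique(col)) {
      cnt <- sum(col == sym)
      if (cnt > best_n) { best <- sym; best_n <- cnt; tie <- FALSE }
      else if (cnt == best_n) tie <- TRUE
    }
    out[j] <- if (tie || best_n / length(col) < threshold) "X" else best
  }
  paste(out, collapse = "")
}

# Random peptide over the 20 amino acids.
random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Render a noise-free two-channel movie with disks at given centres
# (controlled geometry for segmentation tests).
make_disk_movie <- function(centers, radius = 6, height_px = 96,
                            width_px = 96, n_frames = 11, f0 = 100,
                            background = 10, psf_sigma = radius / 3,
                            noise_sd = 0, seed = 1) {
  disks <- matrix(0, height_px, width_px)
  for (i in seq_len(nrow(centers))) {
    px <- cell_pixels(centers[i, 1], centers[i, 2], radius,
                      height_px, width_px)
    disks[px] <- disks[px] + f0
  }
  static <- background + sonopipe:::gaussian_blur(disks, psf_sigma)
  arr <- array(rep(static, n_frames),
               dim = c(height_px, width_px, n_frames))
  if (noise_sd > 0) {
    set.seed(seed)
    arr <- arr + array(rnorm(length(arr), sd = noise_sd), dim = dim(arr))
  }
  imaging_movie(arr, arr, frame_rate_hz = 16.6, stimulus_onsets_s = 0.1)
}

# Type/rowname-normalised hit tables for implementation-vs-oracle comparison.
normalise_hits <- function(df) {
  df <- as.data.frame(df)
  rownames(df) <- NULL
  for (nm in c("start", "end", "central")) df[[nm]] <- as.numeric(df[[nm]])
  df
}
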