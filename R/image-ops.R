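# Low-level grid operations used by the simulator and the segmentation chain.
# No image-processing package ships in the target environment, so these are
# implemented here and validated against geometric oracles in the tests.

# Shift a matrix by (dr, dc) with edge replication.
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian blur, kernel truncated at 3 sigma, replicate padding.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m, (-half:half)[i], 0L)
  res <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) res <- res + k[i] * shift_mat(out, 0L, (-half:half)[i])
  res
}

# Grey-scale erosion/dilation with a (2r+1)-square structuring element,
# built from shifted pmin/pmax (separable: rows then columns).
grey_erode <- function(m, r) {
  out <- m
  for (d in seq_len(r)) out <- pmin(out, shift_mat(m, d, 0L), shift_mat(m, -d, 0L))
  res <- out
  for (d in seq_len(r)) res <- pmin(res, shift_mat(out, 0L, d), shift_mat(out, 0L, -d))
  res
}

grey_dilate <- function(m, r) {
  out <- m
  for (d in seq_len(r)) out <- pmax(out, shift_mat(m, d, 0L), shift_mat(m, -d, 0L))
  res <- out
  for (d in seq_len(r)) res <- pmax(res, shift_mat(out, 0L, d), shift_mat(out, 0L, -d))
  res
}

# Morphological opening used as background estimate ("rolling-ball"-style
# background subtraction with a square window).
grey_opening <- function(m, r) grey_dilate(grey_erode(m, r), r)

# Otsu's threshold on a 256-bin histogram; returns the threshold value.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}

# Lower-envelope-of-parabolas 1-D squared distance transform.
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Exact Euclidean distance transform of a logical mask: distance from each
# TRUE pixel to the nearest FALSE pixel (0 on background).
distance_transform <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  f <- matrix(ifelse(mask, 1e12, 0), h, w)
  for (j in seq_len(w)) f[, j] <- dt1d(f[, j])
  for (i in seq_len(h)) f[i, ] <- dt1d(f[i, ])
  sqrt(pmin(f, 1e12))
}

# 8-connected component labelling of a logical mask (BFS over foreground).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  fg <- which(mask)
  for (p in fg) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p; lab[p] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- ((q - 1L) %% h) + 1L; cc <- ((q - 1L) %/% h) + 1L
      rr <- r + nb_dr; ccn <- cc + nb_dc
      ok <- rr >= 1L & rr <= h & ccn >= 1L & ccn <= w
      idx <- rr[ok] + (ccn[ok] - 1L) * h
      idx <- idx[mask[idx] & lab[idx] == 0L]
      if (length(idx)) { lab[idx] <- cur; queue <- c(queue, idx) }
    }
  }
  lab
}

# Seed detection: local maxima of the distance map within a (2s+1) window,
# greedily thinned so no two seeds are closer than `min_sep` pixels.
find_seeds <- function(dist, min_sep) {
  s <- max(1L, floor(min_sep / 2))
  dil <- grey_dilate(dist, s)
  cand <- which(dist > 0 & dist >= dil - 1e-9)
  if (!length(cand)) return(integer())
  cand <- cand[order(dist[cand], decreasing = TRUE)]
  h <- nrow(dist)
  rr <- ((cand - 1L) %% h) + 1L; cc <- ((cand - 1L) %/% h) + 1L
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    sel <- which(keep)
    if (all((rr[i] - rr[sel])^2 + (cc[i] - cc[sel])^2 >= min_sep^2)) {
      keep[i] <- TRUE
    }
  }
  cand[keep]
}

# Distance-transform watershed: connected components of the mask; any
# component holding more than one seed is split by nearest-seed assignment.
watershed_labels <- function(mask, min_sep) {
  h <- nrow(mask)
  comp <- label_components(mask)
  dist <- distance_transform(mask)
  seeds <- find_seeds(dist, min_sep)
  lab <- matrix(0L, h, ncol(mask))
  nxt <- 0L
  for (cid in seq_len(max(comp, 0L))) {
    px <- which(comp == cid)
    sd_here <- seeds[comp[seeds] == cid]
    if (length(sd_here) <= 1L) {
      nxt <- nxt + 1L
      lab[px] <- nxt
    } else {
      pr <- ((px - 1L) %% h) + 1L; pc <- ((px - 1L) %/% h) + 1L
      sr <- ((sd_here - 1L) %% h) + 1L; sc <- ((sd_here - 1L) %/% h) + 1L
      d2 <- outer(pr, sr, function(a, b) (a - b)^2) +
        outer(pc, sc, function(a, b) (a - b)^2)
      assign_to <- max.col(-d2, ties.method = "first")
      for (k in seq_along(sd_here)) {
        nxt <- nxt + 1L
        lab[px[assign_to == k]] <- nxt
      }
    }
  }
  lab
}
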