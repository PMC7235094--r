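# Independent reference implementations used as oracles. These deliberately
# use different algorithms / code paths than the package internals.

# brute-force non-flat ball morphology (direct definition)
ref_morph_ball <- function(img, radius, dilate) {
  nr <- nrow(img); nc <- ncol(img); r <- floor(radius)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- if (dilate) -Inf else Inf
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > radius^2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      h <- sqrt(radius^2 - di^2 - dj^2) - radius
      v <- if (dilate) img[ii, jj] + h else img[ii, jj] - h
      acc <- if (dilate) max(acc, v) else min(acc, v)
    }
    out[i, j] <- acc
  }
  out
}

ref_rolling_ball_subtract <- function(img, radius) {
  bg <- ref_morph_ball(ref_morph_ball(img, radius, FALSE), radius, TRUE)
  pmax(img - bg, 0)
}

# numeric solve of the moment-preservation equations (polyroot + scan),
# returning the 1-based histogram bin of the cut
oracle_moments_bin <- function(counts) {
  z <- seq_along(counts) - 0.5
  p <- counts / sum(counts)
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  cd <- m2 - m1^2
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  roots <- sort(Re(polyroot(c(c0, c1, 1))))
  p0 <- (roots[2] - m1) / (roots[2] - roots[1])
  which.min(abs(cumsum(p) - p0))
}

# exhaustive scan of the minimum-cross-entropy objective over all cuts
oracle_li_bin <- function(counts) {
  z <- seq_along(counts) - 0.5
  p <- counts / sum(counts)
  n <- length(z)
  obj <- vapply(seq_len(n - 1L), function(t) {
    b <- seq_len(t); a <- seq(t + 1L, n)
    if (sum(p[b]) == 0 || sum(p[a]) == 0) return(Inf)
    mb <- sum(p[b] * z[b]) / sum(p[b])
    ma <- sum(p[a] * z[a]) / sum(p[a])
    -(sum(p[b] * z[b]) * log(mb) + sum(p[a] * z[a]) * log(ma))
  }, numeric(1))
  which.min(obj)
}

# histogram a pixel matrix exactly as the package does (256 bins, min-max)
hist256_counts <- function(px) {
  lo <- min(px); hi <- max(px); w <- (hi - lo) / 256
  bin <- pmin(pmax(floor((px - lo) / w), 0), 255)
  tabulate(as.integer(bin) + 1L, nbins = 256L)
}

# two threshold bins are equivalent when they binarise identically
same_binarisation <- function(counts, bin_a, bin_b) {
  cum <- cumsum(counts)
  cum[bin_a] == cum[bin_b]
}

# O(n^2) brute-force nearest-neighbour tables
ref_nearest_neighbors <- function(psd_pts, astro_pts, k = 10L, radius_um = 3) {
  lapply(seq_len(nrow(psd_pts)), function(i) {
    d <- numeric(nrow(astro_pts))
    for (j in seq_len(nrow(astro_pts))) {
      d[j] <- sqrt((psd_pts$x_um[i] - astro_pts$x_um[j])^2 +
                     (psd_pts$y_um[i] - astro_pts$y_um[j])^2)
    }
    ds <- sort(d)[seq_len(min(k, length(d)))]
    list(nn = c(ds, rep(NA_real_, k - length(ds))),
         count = sum(d <= radius_um))
  })
}

# closed-form 2x2 Pearson chi-squared
ref_chi2_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d))
}

# single-NC scene helper for rendering closed-form checks
single_nc_scene <- function(cx, cy, fwhm_long, fwhm_short = fwhm_long,
                            theta = 0, amplitude = 1e4, field = c(4, 4),
                            background = 0) {
  ground_truth_scene(
    psds = tibble::tibble(id = 1L, x_um = cx, y_um = cy,
                          lamina = NA_character_, bouton_id = NA_integer_,
                          astro_id = NA_integer_, diffuse_amplitude = 0,
                          diffuse_sigma_nm = 0),
    ncs = tibble::tibble(id = 1L, psd_id = 1L, x_um = cx, y_um = cy,
                         fwhm_long_nm = fwhm_long, fwhm_short_nm = fwhm_short,
                         theta = theta, amplitude = amplitude),
    field_um = field, background_rate = background)
}

noiseless <- function(modality, psf_fwhm_nm = NULL) {
  render_spec(modality, psf_fwhm_nm = psf_fwhm_nm, poisson = FALSE,
              read_noise_sd = 0)
}

SIGMA_TO_FWHM <- 2 * sqrt(2 * log(2))
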