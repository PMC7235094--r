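#' Rendering specification
#'
#' Describes how a channel is imaged: pixel pitch, point spread function
#' (PSF) width, noise and bit depth. The three presets mirror the
#' acquisition modalities of the reference protocol: the high-resolution
#' mapping camera (102.4 nm pixels, ~320 nm lateral resolution), confocal
#' (~250 nm resolution) and gated STED (~80 nm resolution), the latter two
#' sampled at 19.97 nm pixels. A `psf_fwhm_nm` of 0 renders an ideal
#' (delta-PSF) image, which is useful for closed-form checks.
#'
#' @param modality `"highres"`, `"confocal"` or `"sted"`.
#' @param pixel_size_nm pixel pitch in nm (preset per modality).
#' @param psf_fwhm_nm Gaussian PSF full width at half maximum in nm.
#' @param poisson apply Poisson shot noise?
#' @param read_noise_sd additive Gaussian read noise standard deviation.
#' @param bit_depth detector bit depth; rendered values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param size_cap_px refuse to render grids larger than this on a side.
#' @return A `render_spec` list.
#' @export
render_spec <- function(modality = c("highres", "confocal", "sted"),
                        pixel_size_nm = NULL, psf_fwhm_nm = NULL,
                        poisson = TRUE, read_noise_sd = 2,
                        bit_depth = 16L, size_cap_px = 4096L) {
  modality <- match.arg(modality)
  defaults <- list(highres = c(px = 102.4, psf = 320),
                   confocal = c(px = 19.97, psf = 250),
                   sted = c(px = 19.97, psf = 80))[[modality]]
  pixel_size_nm <- pixel_size_nm %||% defaults[["px"]]
  psf_fwhm_nm <- psf_fwhm_nm %||% defaults[["psf"]]
  if (pixel_size_nm <= 0) stop("`pixel_size_nm` must be positive", call. = FALSE)
  if (psf_fwhm_nm < 0) stop("`psf_fwhm_nm` must be >= 0", call. = FALSE)
  if (read_noise_sd < 0) stop("`read_noise_sd` must be >= 0", call. = FALSE)
  structure(list(modality = modality, pixel_size_nm = pixel_size_nm,
                 psf_fwhm_nm = psf_fwhm_nm, poisson = poisson,
                 read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth),
                 size_cap_px = as.integer(size_cap_px)),
            class = "render_spec")
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# collect the elliptical-Gaussian components a channel renders:
# columns x_um, y_um, sig_long_nm, sig_short_nm, theta, amplitude
channel_components <- function(scene, channel) {
  switch(channel,
    psd95 = {
      nc_part <- tibble::tibble(
        x_um = scene$ncs$x_um, y_um = scene$ncs$y_um,
        sig_long_nm = scene$ncs$fwhm_long_nm * FWHM_TO_SIGMA,
        sig_short_nm = scene$ncs$fwhm_short_nm * FWHM_TO_SIGMA,
        theta = scene$ncs$theta, amplitude = scene$ncs$amplitude)
      pd <- scene$psds
      if (!is.null(pd$diffuse_amplitude)) {
        keep <- !is.na(pd$diffuse_amplitude) & pd$diffuse_amplitude > 0
        nc_part <- dplyr::bind_rows(nc_part, tibble::tibble(
          x_um = pd$x_um[keep], y_um = pd$y_um[keep],
          sig_long_nm = pd$diffuse_sigma_nm[keep],
          sig_short_nm = pd$diffuse_sigma_nm[keep],
          theta = 0, amplitude = pd$diffuse_amplitude[keep]))
      }
      nc_part
    },
    vglut1 = ,
    vglut2 = {
      keep <- scene$boutons$id[scene$boutons$class == channel]
      s <- scene$bouton_subs[scene$bouton_subs$bouton_id %in% keep, ]
      tibble::tibble(x_um = s$x_um, y_um = s$y_um,
                     sig_long_nm = s$diameter_nm * FWHM_TO_SIGMA,
                     sig_short_nm = s$diameter_nm * FWHM_TO_SIGMA,
                     theta = 0, amplitude = s$amplitude)
    },
    astro = tibble::tibble(
      x_um = scene$astros$x_um, y_um = scene$astros$y_um,
      sig_long_nm = scene$astros$diameter_nm * FWHM_TO_SIGMA,
      sig_short_nm = scene$astros$diameter_nm * FWHM_TO_SIGMA,
      theta = 0, amplitude = scene$astros$amplitude),
    stop("unknown channel: ", channel, call. = FALSE)
  )
}

#' Render a scene channel into a noisy image
#'
#' Every object is an anisotropic 2-D Gaussian profile carrying its
#' amplitude as total photons. Convolution with the Gaussian PSF is applied
#' analytically (variances add), so the noiseless image integrates to
#' `background * n_pixels + sum(amplitudes)` for objects fully inside the
#' frame. Poisson shot noise is applied per pixel, then Gaussian read
#' noise, then values are clipped to the detector range.
#'
#' @param scene a [ground_truth_scene()].
#' @param channel `"psd95"`, `"vglut1"`, `"vglut2"` or `"astro"`.
#' @param spec a [render_spec()].
#' @param seed integer seed for the noise draws; omit (`NULL`) together
#'   with `poisson = FALSE, read_noise_sd = 0` for a noiseless render.
#' @return A [channel_image()].
#' @export
render_channel <- function(scene, channel = c("psd95", "vglut1", "vglut2", "astro"),
                           spec = render_spec(), seed = NULL) {
  stopifnot(inherits(scene, "ground_truth_scene"), inherits(spec, "render_spec"))
  channel <- match.arg(channel)
  s_nm <- spec$pixel_size_nm
  npx <- ceiling(scene$field_um * 1000 / s_nm) # c(x, y)
  if (any(npx > spec$size_cap_px)) {
    stop(sprintf("pixel grid %d x %d exceeds the size cap (%d)",
                 npx[1], npx[2], spec$size_cap_px), call. = FALSE)
  }
  img <- matrix(scene$background_rate, nrow = npx[2], ncol = npx[1])
  comp <- channel_components(scene, channel)
  sig_psf <- spec$psf_fwhm_nm * FWHM_TO_SIGMA
  for (i in seq_len(nrow(comp))) {
    img <- add_gaussian_component(
      img, s_nm, x_nm = comp$x_um[i] * 1000, y_nm = comp$y_um[i] * 1000,
      sig_l = comp$sig_long_nm[i], sig_s = comp$sig_short_nm[i],
      theta = comp$theta[i], amp = comp$amplitude[i], sig_psf = sig_psf)
  }
  if (spec$poisson || spec$read_noise_sd > 0) {
    if (is.null(seed)) {
      stop("`seed` is required when noise is enabled", call. = FALSE)
    }
    img <- withr::with_seed(as.integer(seed), {
      out <- img
      if (spec$poisson) {
        out <- matrix(stats::rpois(length(out), pmax(out, 0)),
                      nrow = nrow(out))
      }
      if (spec$read_noise_sd > 0) {
        out <- out + stats::rnorm(length(out), 0, spec$read_noise_sd)
      }
      out
    })
  }
  img <- pmin(pmax(img, 0), 2^spec$bit_depth - 1)
  channel_image(img, s_nm, spec$modality, channel)
}

# add one elliptical Gaussian (post-PSF) to the image, evaluated over a
# +/- 6 sigma bounding box; pixel [r, c] centre is at ((c-.5)s, (r-.5)s) nm
add_gaussian_component <- function(img, s_nm, x_nm, y_nm, sig_l, sig_s,
                                   theta, amp, sig_psf) {
  v_l <- sig_l^2 + sig_psf^2
  v_s <- sig_s^2 + sig_psf^2
  ct <- cos(theta); st <- sin(theta)
  # covariance in the frame axes
  sxx <- v_l * ct^2 + v_s * st^2
  syy <- v_l * st^2 + v_s * ct^2
  sxy <- (v_l - v_s) * ct * st
  det_s <- sxx * syy - sxy^2
  ext <- 6 * sqrt(max(v_l, v_s))
  c_lo <- max(1L, floor((x_nm - ext) / s_nm + 0.5))
  c_hi <- min(ncol(img), ceiling((x_nm + ext) / s_nm + 0.5))
  r_lo <- max(1L, floor((y_nm - ext) / s_nm + 0.5))
  r_hi <- min(nrow(img), ceiling((y_nm + ext) / s_nm + 0.5))
  if (c_lo > c_hi || r_lo > r_hi) return(img)
  dx <- (seq(c_lo, c_hi) - 0.5) * s_nm - x_nm
  dy <- (seq(r_lo, r_hi) - 0.5) * s_nm - y_nm
  # quadratic form d' Sigma^{-1} d, vectorised over the grid
  inv_xx <- syy / det_s; inv_yy <- sxx / det_s; inv_xy <- -sxy / det_s
  qf <- outer(dy^2 * inv_yy, dx^2 * inv_xx, "+") +
    2 * inv_xy * outer(dy, dx)
  patch <- amp * s_nm^2 / (2 * pi * sqrt(det_s)) * exp(-0.5 * qf)
  img[r_lo:r_hi, c_lo:c_hi] <- img[r_lo:r_hi, c_lo:c_hi] + patch
  img
}
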