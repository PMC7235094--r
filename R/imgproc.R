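#' Pipeline constants
#'
#' All numeric constants of the segmentation and colocalization procedure in
#' one place. Defaults are the published protocol values: 10 px rolling-ball
#' radius for punctate channels and 25 px for GFAP processes, a 1.5 px
#' Gaussian smoothing, moment-preserving ("Moments") thresholding for
#' punctate channels and minimum-cross-entropy ("Li") for GFAP, an 8 px
#' minimum particle size for nanocluster detection, a 1 px overlap rule for
#' colocalization, 10 nearest neighbours, a 3 um counting radius, a 200 nm
#' edge-edge limit, and a 180 degree rotation for the spatial null.
#'
#' @param bg_radius_punctate,bg_radius_gfap rolling-ball radii in pixels.
#' @param gaussian_sigma Gaussian smoothing sigma in pixels.
#' @param threshold_punctate,threshold_gfap auto-threshold method per role.
#' @param min_particle_px minimum particle size (pixels) for nanocluster
#'   detection.
#' @param min_psd_px minimum particle size for PSD-scale detection. The
#'   protocol states a minimum only for the nanocluster macro; at PSD scale a
#'   2 px floor is applied to suppress single-pixel noise (configurable).
#' @param overlap_min_px minimum pixel overlap for object colocalization.
#' @param nn_k number of nearest neighbours retained per PSD.
#' @param radius_count_um counting radius in micrometres.
#' @param edge_edge_max_nm edge-edge distance limit in nanometres.
#' @param rotation_deg rotation of the spatial null control.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bg_radius_punctate = 10,
                            bg_radius_gfap = 25,
                            gaussian_sigma = 1.5,
                            threshold_punctate = "moments",
                            threshold_gfap = "li",
                            min_particle_px = 8L,
                            min_psd_px = 2L,
                            overlap_min_px = 1L,
                            nn_k = 10L,
                            radius_count_um = 3.0,
                            edge_edge_max_nm = 200,
                            rotation_deg = 180) {
  cfg <- list(bg_radius_punctate = bg_radius_punctate,
              bg_radius_gfap = bg_radius_gfap,
              gaussian_sigma = gaussian_sigma,
              threshold_punctate = threshold_punctate,
              threshold_gfap = threshold_gfap,
              min_particle_px = as.integer(min_particle_px),
              min_psd_px = as.integer(min_psd_px),
              overlap_min_px = as.integer(overlap_min_px),
              nn_k = as.integer(nn_k),
              radius_count_um = radius_count_um,
              edge_edge_max_nm = edge_edge_max_nm,
              rotation_deg = rotation_deg)
  num <- vapply(cfg[!names(cfg) %in% c("threshold_punctate", "threshold_gfap")],
                as.numeric, numeric(1))
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all pipeline constants must be positive", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background as the grayscale opening of the
#' image with a non-flat hemispherical (ball) structuring element of the
#' given radius — the rolling-ball construction in (x, y, intensity) space,
#' with ball height in intensity units numerically equal to pixel units —
#' and subtracts it, clipping at zero. The background envelope never exceeds
#' the image, so the output is `<=` the input everywhere.
#'
#' @param image a [channel_image()].
#' @param radius_px ball radius in pixels (10 for punctate channels, 25 for
#'   GFAP in the reference protocol).
#' @return A background-subtracted [channel_image()].
#' @export
subtract_background <- function(image, radius_px) {
  stopifnot(inherits(image, "channel_image"))
  if (!is.numeric(radius_px) || length(radius_px) != 1L || radius_px <= 0) {
    stop("`radius_px` must be a single positive number", call. = FALSE)
  }
  eroded <- morph_ball_cpp(image$pixels, radius_px, FALSE)
  bg <- morph_ball_cpp(eroded, radius_px, TRUE)
  out <- pmax(image$pixels - bg, 0)
  channel_image(out, image$pixel_size_nm, image$modality, image$label)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with reflective (mirror) padding; conserves the
# total image sum exactly up to floating point.
convolve_sep_reflect <- function(px, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  reflect_idx <- function(n) {
    k <- min(r, n)
    c(seq(k, 1), seq_len(n), seq(n, n - k + 1)) # half-sample mirror
  }
  conv1 <- function(m) { # convolve down columns
    n <- nrow(m)
    mp <- m[reflect_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kernel)) {
      out <- out + kernel[j] * mp[seq_len(n) + (j - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(px))))
}

#' Gaussian smoothing
#'
#' Convolution with a normalised Gaussian kernel (separable, reflective
#' border), conserving total intensity.
#'
#' @param image a [channel_image()].
#' @param sigma_px Gaussian sigma in pixels (default 1.5, the protocol's
#'   "1.5 pixel" smoothing, interpreted as sigma).
#' @return A smoothed [channel_image()].
#' @export
gaussian_smooth <- function(image, sigma_px = 1.5) {
  stopifnot(inherits(image, "channel_image"))
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || sigma_px <= 0) {
    stop("`sigma_px` must be a single positive number", call. = FALSE)
  }
  out <- convolve_sep_reflect(image$pixels, gaussian_kernel_1d(sigma_px))
  out[out < 0] <- 0
  channel_image(out, image$pixel_size_nm, image$modality, image$label)
}

# 256-bin histogram over the min-max intensity range. Returns counts,
# bin centres and the upper bin edges used to map a bin cut back to an
# intensity threshold.
histogram256 <- function(px) {
  lo <- min(px); hi <- max(px)
  if (hi <= lo) {
    stop("degenerate histogram: image has a single grey level", call. = FALSE)
  }
  w <- (hi - lo) / 256
  bin <- pmin(pmax(floor((px - lo) / w), 0), 255)
  counts <- tabulate(as.integer(bin) + 1L, nbins = 256L)
  list(counts = counts,
       centres = lo + (seq_len(256) - 0.5) * w,
       upper_edges = lo + seq_len(256) * w,
       lo = lo, width = w)
}

# Moment-preserving (Tsai) threshold on a 256-bin histogram given as counts
# with grey values `z` (bin centres). Returns the index (1..256) of the last
# below-threshold bin.
moments_threshold_bin <- function(counts, z = seq_len(length(counts)) - 1) {
  p <- counts / sum(counts)
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  cd <- m2 - m1^2
  if (cd <= 0) stop("degenerate histogram: zero variance", call. = FALSE)
  # two representative levels z0 < z1 preserving the first three moments
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- sqrt(max(c1^2 - 4 * c0, 0))
  z0 <- (-c1 - disc) / 2
  z1 <- (-c1 + disc) / 2
  p0 <- (z1 - m1) / (z1 - z0) # fraction of pixels assigned the lower level
  cum <- cumsum(p)
  # the cut whose below-fraction is closest to p0
  which.min(abs(cum - p0))
}

# Li minimum-cross-entropy threshold on grey values `z` (must be > 0).
# The cross-entropy objective can hold several stationary points of the
# classical mean-based fixed point t <- (mu_b - mu_a)/(log mu_b - log mu_a),
# and the iteration started from the global mean sometimes settles in a
# non-global one. The objective is first scanned over every histogram cut
# (cheap: 255 evaluations) to locate the global minimum's bin, then the
# fixed point is iterated from that bin's centre; if the iterate wanders
# out of the bracketing bins the scanned cut is kept.
li_threshold_value <- function(counts, z, tol = 1e-4, max_iter = 200L) {
  stopifnot(all(z > 0))
  p <- counts / sum(counts)
  n <- length(z)
  pz <- p * z
  cum_p <- cumsum(p); cum_pz <- cumsum(pz)
  obj <- rep(Inf, n - 1L)
  valid <- cum_p > 0 & cum_p < 1
  t_idx <- which(valid[-n])
  mb <- cum_pz[t_idx] / cum_p[t_idx]
  ma <- (cum_pz[n] - cum_pz[t_idx]) / (1 - cum_p[t_idx])
  obj[t_idx] <- -(cum_pz[t_idx] * log(mb) + (cum_pz[n] - cum_pz[t_idx]) * log(ma))
  bin <- which.min(obj)
  t_cur <- z[bin]
  for (i in seq_len(max_iter)) {
    below <- z <= t_cur
    if (!any(below) || all(below)) break
    mb1 <- sum(pz[below]) / sum(p[below])
    ma1 <- sum(pz[!below]) / sum(p[!below])
    t_new <- if (abs(ma1 - mb1) < .Machine$double.eps) t_cur else
      (mb1 - ma1) / (log(mb1) - log(ma1))
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  # accept the polished value only when its cut attains exactly the scanned
  # minimum (the objective is exactly flat across empty histogram gaps,
  # where every cut binarises identically); otherwise keep the scanned cut
  w <- if (n > 1) z[2] - z[1] else 1
  b2 <- min(max(floor((t_cur - z[1]) / w) + 1L, 1L), n - 1L)
  if (is.finite(obj[b2]) && obj[b2] <= obj[bin]) t_cur else z[bin] + w / 2
}

#' Automatic thresholds
#'
#' `threshold_moments()` computes the moment-preserving ("Moments")
#' threshold of Tsai: the binarisation level such that a two-level surrogate
#' image preserves the first three grey-level moments of the original. It is
#' computed on a 256-bin histogram over the image's min-max range; the
#' returned value is the upper edge of the last below-threshold bin, and
#' foreground is `pixels > threshold`.
#'
#' `threshold_li()` computes the Li minimum-cross-entropy threshold: the
#' level minimising the cross-entropy between the image and its two-level
#' surrogate. The global minimum is located by scanning every histogram
#' cut, then polished with the classical mean-based fixed-point update
#' (which alone can settle in a non-global stationary point on strongly
#' bimodal histograms). Because the objective takes logarithms of grey
#' values, the computation runs on bin centres shifted to strictly
#' positive support and the result is mapped back to the original
#' intensity scale.
#'
#' @param image a [channel_image()], or a bare numeric matrix.
#' @return The threshold as a single number on the image's intensity scale,
#'   with attribute `"bin"` giving the 1-based histogram bin of the cut.
#' @export
threshold_moments <- function(image) {
  px <- if (inherits(image, "channel_image")) image$pixels else image
  h <- histogram256(px)
  bin <- moments_threshold_bin(h$counts, h$centres)
  structure(h$upper_edges[bin], bin = bin)
}

#' @rdname threshold_moments
#' @export
threshold_li <- function(image) {
  px <- if (inherits(image, "channel_image")) image$pixels else image
  h <- histogram256(px)
  z <- seq_len(256) - 0.5 # positive bin-centre scale
  t_bin <- li_threshold_value(h$counts, z)
  # last below-threshold bin: bins whose centre lies at or below the cut
  bin <- min(max(floor(t_bin + 0.5), 1L), 255L)
  structure(h$lo + t_bin * h$width, bin = bin)
}

#' Particle detection by connected components
#'
#' Labels 8-connected foreground components and discards those smaller than
#' `min_px` pixels (the nanocluster macro's "8-Infinity" size filter).
#' Surviving labels are renumbered densely in raster scan order.
#'
#' @param mask a [binary_mask()].
#' @param min_px minimum object size in pixels.
#' @return A [label_image()].
#' @export
detect_particles <- function(mask, min_px = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (min_px < 1L) stop("`min_px` must be >= 1", call. = FALSE)
  lab <- label_components_cpp(mask$pixels)
  n <- attr(lab, "n")
  if (n > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(sizes >= min_px)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  label_image(lab, mask$pixel_size_nm)
}

#' Measure labelled objects on the raw image
#'
#' Mean intensity is taken from the raw (pre-processing-free) image under
#' each label — measurements are redirected back to the original data, so
#' background subtraction and smoothing only affect segmentation, never the
#' reported intensities. Centroids are geometric pixel centroids in
#' physical micrometres; `integrated_intensity = mean_intensity *
#' pixel_count` by construction.
#'
#' @param labels a [label_image()].
#' @param raw the raw [channel_image()] the labels were derived from.
#' @return A tibble with one row per object: `id`, `pixel_count`,
#'   `area_um2`, `x_um`, `y_um`, `mean_intensity`, `integrated_intensity`,
#'   `on_border`.
#' @export
measure_objects <- function(labels, raw) {
  stopifnot(inherits(labels, "label_image"), inherits(raw, "channel_image"))
  if (!identical(dim(labels$pixels), dim(raw$pixels))) {
    stop("labels and raw image differ in shape", call. = FALSE)
  }
  n <- labels$n
  s_um <- labels$pixel_size_nm / 1000
  if (n == 0L) {
    return(tibble::tibble(id = integer(), pixel_count = integer(),
                          area_um2 = numeric(), x_um = numeric(),
                          y_um = numeric(), mean_intensity = numeric(),
                          integrated_intensity = numeric(),
                          on_border = logical()))
  }
  idx <- which(labels$pixels > 0L)
  lb <- labels$pixels[idx]
  nr <- nrow(labels$pixels)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  counts <- tabulate(lb, nbins = n)
  sum_raw <- as.numeric(rowsum(raw$pixels[idx], lb, reorder = TRUE))
  mean_int <- sum_raw / counts
  x_um <- as.numeric(rowsum(cc - 0.5, lb)) / counts * s_um
  y_um <- as.numeric(rowsum(rr - 0.5, lb)) / counts * s_um
  border <- rr == 1L | rr == nr | cc == 1L | cc == ncol(labels$pixels)
  on_border <- as.logical(rowsum(as.numeric(border), lb) > 0)
  tibble::tibble(id = seq_len(n), pixel_count = as.integer(counts),
                 area_um2 = counts * s_um^2, x_um = x_um, y_um = y_um,
                 mean_intensity = mean_int,
                 integrated_intensity = mean_int * counts,
                 on_border = on_border)
}

#' Segment one channel with the role-appropriate constants
#'
#' Composes the full detection chain: rolling-ball background subtraction,
#' Gaussian smoothing, auto-thresholding, particle detection and
#' raw-intensity measurement. The `role` selects the protocol constants:
#' punctate channels use the 10 px ball and Moments thresholding; GFAP uses
#' the 25 px ball and Li thresholding; `"vglut2_manual"` is punctate
#' processing with a user-supplied threshold override (some VGLUT2 images
#' need manual adjustment).
#'
#' @param image raw [channel_image()].
#' @param config a [pipeline_config()].
#' @param role `"punctate"`, `"gfap"` or `"vglut2_manual"`.
#' @param threshold_override numeric threshold on the processed-image scale,
#'   required for `"vglut2_manual"`.
#' @param min_px minimum particle size; defaults to `config$min_psd_px`.
#' @param max_foreground_frac sanity cap on the foreground fraction.
#'   Punctate binarization presupposes sparse foreground; on a channel with
#'   no real signal the auto-threshold falls inside the noise mode and
#'   binarizes a large share of the image. Above the cap the segmentation
#'   is declared degenerate: empty result, with a warning.
#' @return A list with elements `mask` ([binary_mask()]), `labels`
#'   ([label_image()]), `objects` (tibble from [measure_objects()]),
#'   `threshold` and `method`.
#' @export
segment_channel <- function(image, config = pipeline_config(),
                            role = c("punctate", "gfap", "vglut2_manual"),
                            threshold_override = NULL,
                            min_px = NULL, max_foreground_frac = 0.25) {
  role <- match.arg(role)
  radius <- if (role == "gfap") config$bg_radius_gfap else config$bg_radius_punctate
  method <- switch(role, punctate = config$threshold_punctate,
                   gfap = config$threshold_gfap, vglut2_manual = "manual")
  if (is.null(min_px)) min_px <- config$min_psd_px
  proc <- gaussian_smooth(subtract_background(image, radius),
                          config$gaussian_sigma)
  thr <- if (role == "vglut2_manual") {
    if (is.null(threshold_override)) {
      stop("role 'vglut2_manual' requires `threshold_override`", call. = FALSE)
    }
    threshold_override
  } else {
    res <- try(switch(method, moments = threshold_moments(proc),
                      li = threshold_li(proc)), silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("degenerate histogram; returning empty segmentation")
      NA_real_
    } else as.numeric(res)
  }
  fg <- if (is.na(thr)) {
    matrix(FALSE, nrow(image$pixels), ncol(image$pixels))
  } else proc$pixels > thr
  if (mean(fg) > max_foreground_frac) {
    warning(sprintf(
      "foreground fraction %.2f exceeds %.2f; channel '%s' has no sparse signal, returning empty segmentation",
      mean(fg), max_foreground_frac, image$label))
    fg <- matrix(FALSE, nrow(image$pixels), ncol(image$pixels))
    thr <- NA_real_
  }
  mask <- binary_mask(fg, image$pixel_size_nm,
                      provenance = list(label = image$label, method = method,
                                        threshold = thr))
  labels <- detect_particles(mask, min_px)
  list(mask = mask, labels = labels,
       objects = measure_objects(labels, image),
       threshold = thr, method = method)
}
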