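#' Assign STED nanoclusters to their parent confocal PSDs
#'
#' Each nanocluster (NC) segmented at STED resolution is assigned to the
#' PSD whose confocal-resolution mask contains the majority of the NC's
#' pixels (evaluated by mapping NC pixel centres into the PSD grid through
#' physical coordinates). Ties are broken towards the lower PSD id; NCs
#' with no overlapping PSD get parent `NA` and never contribute to per-PSD
#' counts. The two inputs must cover the same physical frame — confocal
#' and STED acquisitions share stage coordinates, so no registration is
#' performed.
#'
#' @param psd_labels a [label_image()] of PSDs (coarse grid).
#' @param nc_labels a [label_image()] of NCs (fine grid).
#' @return A tibble: `nc_id`, `psd_id` (`NA` for orphans), `overlap_px`,
#'   `total_px`.
#' @export
assign_ncs_to_psds <- function(psd_labels, nc_labels) {
  stopifnot(inherits(psd_labels, "label_image"), inherits(nc_labels, "label_image"))
  ext_psd <- physical_extent_um(psd_labels)
  ext_nc <- physical_extent_um(nc_labels)
  if (any(abs(ext_psd - ext_nc) > psd_labels$pixel_size_nm / 1000)) {
    stop("PSD and NC images do not cover the same physical frame", call. = FALSE)
  }
  n_nc <- nc_labels$n
  if (n_nc == 0L) {
    return(tibble::tibble(nc_id = integer(), psd_id = integer(),
                          overlap_px = integer(), total_px = integer()))
  }
  idx <- which(nc_labels$pixels > 0L)
  lb <- nc_labels$pixels[idx]
  nr <- nrow(nc_labels$pixels)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ratio <- nc_labels$pixel_size_nm / psd_labels$pixel_size_nm
  # physical centre of each NC pixel, mapped into the coarse grid
  pr <- pmin(pmax(ceiling((rr - 0.5) * ratio), 1L), nrow(psd_labels$pixels))
  pc <- pmin(pmax(ceiling((cc - 0.5) * ratio), 1L), ncol(psd_labels$pixels))
  parent <- psd_labels$pixels[cbind(pr, pc)]
  tab <- tibble::tibble(nc_id = lb, parent = parent) |>
    dplyr::count(.data$nc_id, .data$parent, name = "n")
  totals <- tab |>
    dplyr::group_by(.data$nc_id) |>
    dplyr::summarise(total_px = sum(.data$n), .groups = "drop")
  best <- tab |>
    dplyr::filter(.data$parent > 0L) |>
    dplyr::group_by(.data$nc_id) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$parent, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  tibble::tibble(nc_id = seq_len(n_nc)) |>
    dplyr::left_join(dplyr::select(best, "nc_id", psd_id = "parent",
                                   overlap_px = "n"), by = "nc_id") |>
    dplyr::left_join(totals, by = "nc_id") |>
    dplyr::mutate(overlap_px = dplyr::coalesce(.data$overlap_px, 0L),
                  psd_id = as.integer(.data$psd_id))
}

#' Classify a PSD by its nanocluster count
#'
#' `0 -> "0NC"`, `1 -> "1NC"`, `2 -> "2NC"`, `>= 3 -> "3plusNC"`. PSDs with
#' zero detected NCs are a degenerate class normally excluded from
#' NC-fraction denominators; the aggregate "2+NC" class used in regional
#' comparisons is `2NC` plus `3plusNC`.
#'
#' @param nc_count integer vector of per-PSD NC counts.
#' @return A factor with levels `0NC`, `1NC`, `2NC`, `3plusNC`.
#' @export
classify_psd <- function(nc_count) {
  if (any(nc_count < 0, na.rm = TRUE)) {
    stop("NC counts cannot be negative", call. = FALSE)
  }
  cls <- dplyr::case_when(nc_count == 0L ~ "0NC",
                          nc_count == 1L ~ "1NC",
                          nc_count == 2L ~ "2NC",
                          nc_count >= 3L ~ "3plusNC")
  factor(cls, levels = c("0NC", "1NC", "2NC", "3plusNC"))
}

#' Per-PSD nanocluster counts and classes
#'
#' @param assignment output of [assign_ncs_to_psds()].
#' @param psd_objects the PSD measurement tibble ([measure_objects()]).
#' @return `psd_objects` with `nc_count` and `nc_class` columns appended.
#' @export
psd_nc_table <- function(assignment, psd_objects) {
  counts <- assignment |>
    dplyr::filter(!is.na(.data$psd_id)) |>
    dplyr::count(.data$psd_id, name = "nc_count")
  psd_objects |>
    dplyr::left_join(counts, by = c(id = "psd_id")) |>
    dplyr::mutate(nc_count = dplyr::coalesce(.data$nc_count, 0L),
                  nc_class = classify_psd(.data$nc_count))
}

# --- sub-pixel image sampling ------------------------------------------------

# sample image values at continuous pixel coordinates (units of pixels,
# pixel [r, c] centre at x = c - 0.5, y = r - 0.5); replicated borders
interp_pixels <- function(px, x, y, method = c("cubic", "bilinear")) {
  method <- match.arg(method)
  nr <- nrow(px); nc <- ncol(px)
  cf <- x + 0.5; rf <- y + 0.5 # fractional matrix indices
  if (method == "bilinear") {
    c0 <- floor(cf); r0 <- floor(rf)
    tc <- cf - c0; tr <- rf - r0
    cl <- function(i, n) pmin(pmax(i, 1L), n)
    v00 <- px[cbind(cl(r0, nr), cl(c0, nc))]
    v01 <- px[cbind(cl(r0, nr), cl(c0 + 1, nc))]
    v10 <- px[cbind(cl(r0 + 1, nr), cl(c0, nc))]
    v11 <- px[cbind(cl(r0 + 1, nr), cl(c0 + 1, nc))]
    return((1 - tr) * ((1 - tc) * v00 + tc * v01) +
             tr * ((1 - tc) * v10 + tc * v11))
  }
  # separable Catmull-Rom cubic
  w_cr <- function(t) {
    cbind(0.5 * (-t^3 + 2 * t^2 - t),
          0.5 * (3 * t^3 - 5 * t^2 + 2),
          0.5 * (-3 * t^3 + 4 * t^2 + t),
          0.5 * (t^3 - t^2))
  }
  c0 <- floor(cf); r0 <- floor(rf)
  tc <- cf - c0; tr <- rf - r0
  wc <- w_cr(tc); wr <- w_cr(tr)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  out <- numeric(length(x))
  for (j in 1:4) { # row offset
    rowv <- numeric(length(x))
    for (i in 1:4) { # col offset
      rowv <- rowv + wc[, i] * px[cbind(cl(r0 + j - 2L, nr), cl(c0 + i - 2L, nc))]
    }
    out <- out + wr[, j] * rowv
  }
  out
}

#' Full width at half maximum along a line profile
#'
#' Samples the image along the segment `p0 -> p1` (physical micrometre
#' endpoints) at quarter-pixel spacing, subtracts a baseline equal to the
#' smaller of the two end values, and returns the distance between the two
#' half-maximum crossings bracketing the profile peak, located by linear
#' interpolation between samples. Returns `NA` when the profile has no
#' two crossings (flat or monotone profiles are unmeasurable).
#'
#' @param image a [channel_image()].
#' @param p0,p1 numeric `c(x, y)` endpoints in micrometres.
#' @param interp sub-pixel sampling scheme; Catmull-Rom cubic by default
#'   (bilinear flattens sharp peaks enough to bias FWHM at STED sampling).
#' @param step_frac sample spacing as a fraction of the pixel pitch.
#' @return FWHM in nanometres, or `NA_real_`.
#' @export
fwhm_profile <- function(image, p0, p1, interp = c("cubic", "bilinear"),
                         step_frac = 0.25) {
  stopifnot(inherits(image, "channel_image"), length(p0) == 2, length(p1) == 2)
  interp <- match.arg(interp)
  s_um <- image$pixel_size_nm / 1000
  ext <- physical_extent_um(image)
  pts <- rbind(p0, p1)
  if (any(pts[, 1] < 0 | pts[, 1] > ext[1] | pts[, 2] < 0 | pts[, 2] > ext[2])) {
    stop("profile endpoints fall outside the image", call. = FALSE)
  }
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(ceiling(len / (s_um * step_frac)), 8L)
  tt <- seq(0, 1, length.out = n + 1L)
  xs <- (p0[1] + tt * (p1[1] - p0[1])) / s_um
  ys <- (p0[2] + tt * (p1[2] - p0[2])) / s_um
  prof <- interp_pixels(image$pixels, xs, ys, interp)
  baseline <- min(prof[1], prof[length(prof)])
  peak_i <- which.max(prof)
  half <- baseline + (prof[peak_i] - baseline) / 2
  if (!(prof[peak_i] > baseline)) return(NA_real_)
  step_um <- len / n
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(peak_i - 1L)) else
      seq_len(length(prof) - peak_i) + peak_i - 1L
    for (i in idx) {
      a <- prof[i]; b <- prof[i + 1L]
      if ((a - half) * (b - half) <= 0 && a != b) {
        frac <- (half - a) / (b - a)
        return((i - 1L + frac) * step_um)
      }
    }
    NA_real_
  }
  left <- cross("left"); right <- cross("right")
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * 1000
}

#' Nanocluster axis lengths by FWHM line profiles
#'
#' For each (isolated) NC the intensity-weighted principal axes are
#' computed from the raw pixels under its label; FWHM is then measured by
#' [fwhm_profile()] along each axis through the intensity-weighted
#' centroid, and reported sorted so that `fwhm_short_nm <= fwhm_long_nm`.
#' NCs with another NC centroid closer than `exclusion_radius_nm` are
#' skipped (mirroring the practice of measuring only NCs that appear
#' alone, to avoid overlapping profiles), as are NCs whose profile has no
#' measurable peak.
#'
#' @param image the raw STED [channel_image()].
#' @param labels an NC [label_image()] on the same grid.
#' @param exclusion_radius_nm isolation radius; default 400 nm.
#' @param interp passed to [fwhm_profile()].
#' @return A tibble: `id`, `fwhm_short_nm`, `fwhm_long_nm`,
#'   `aspect_ratio`, `measured` (FALSE rows record why a skipped NC was
#'   skipped in `reason`).
#' @export
nc_axes <- function(image, labels, exclusion_radius_nm = 400,
                    interp = c("cubic", "bilinear")) {
  stopifnot(inherits(image, "channel_image"), inherits(labels, "label_image"))
  interp <- match.arg(interp)
  n <- labels$n
  empty <- tibble::tibble(id = integer(), fwhm_short_nm = numeric(),
                          fwhm_long_nm = numeric(), aspect_ratio = numeric(),
                          measured = logical(), reason = character())
  if (n == 0L) return(empty)
  s_um <- image$pixel_size_nm / 1000
  obj <- measure_objects(labels, image)
  ext <- physical_extent_um(image)
  rows <- purrr::map(seq_len(n), function(i) {
    # isolation against every other NC centroid
    if (n > 1L) {
      d2 <- (obj$x_um - obj$x_um[i])^2 + (obj$y_um - obj$y_um[i])^2
      d2[i] <- Inf
      if (min(d2) < (exclusion_radius_nm / 1000)^2) {
        return(tibble::tibble(id = i, fwhm_short_nm = NA_real_,
                              fwhm_long_nm = NA_real_, aspect_ratio = NA_real_,
                              measured = FALSE, reason = "not isolated"))
      }
    }
    idx <- which(labels$pixels == i)
    nr <- nrow(labels$pixels)
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    w <- image$pixels[idx]
    if (sum(w) <= 0) {
      return(tibble::tibble(id = i, fwhm_short_nm = NA_real_,
                            fwhm_long_nm = NA_real_, aspect_ratio = NA_real_,
                            measured = FALSE, reason = "zero intensity"))
    }
    xs <- (cc - 0.5) * s_um; ys <- (rr - 0.5) * s_um
    mx <- sum(w * xs) / sum(w); my <- sum(w * ys) / sum(w)
    cxx <- sum(w * (xs - mx)^2) / sum(w)
    cyy <- sum(w * (ys - my)^2) / sum(w)
    cxy <- sum(w * (xs - mx) * (ys - my)) / sum(w)
    eg <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
    half_len <- max(4 * sqrt(eg$values[1]), 6 * s_um)
    fw <- vapply(1:2, function(a) {
      v <- eg$vectors[, a]
      q0 <- c(mx, my) - half_len * v
      q1 <- c(mx, my) + half_len * v
      clamp <- function(q) pmin(pmax(q, c(0, 0)), ext)
      fwhm_profile(image, clamp(q0), clamp(q1), interp = interp)
    }, numeric(1))
    if (anyNA(fw)) {
      return(tibble::tibble(id = i, fwhm_short_nm = NA_real_,
                            fwhm_long_nm = NA_real_, aspect_ratio = NA_real_,
                            measured = FALSE, reason = "no half-max crossings"))
    }
    tibble::tibble(id = i, fwhm_short_nm = min(fw), fwhm_long_nm = max(fw),
                   aspect_ratio = min(fw) / max(fw), measured = TRUE,
                   reason = NA_character_)
  })
  dplyr::bind_rows(rows)
}
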