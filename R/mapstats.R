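#' Laminar ROI polygons
#'
#' A lamina ROI is a simple polygon in physical micrometres labelled with
#' one of the Rexed lamina groups used for spinal grey matter mapping.
#'
#' @param label one of `"I-II"`, `"III-IV"`, `"V"`, `"VI"`, `"VII"`,
#'   `"VIII"`, `"IX"`, `"X"`.
#' @param vertices two-column matrix (or data frame) of `x, y` vertices in
#'   micrometres, unclosed (the closing edge is implicit).
#' @return A `lamina_roi` object with the polygon and its shoelace area.
#' @export
lamina_roi <- function(label, vertices) {
  labels_ok <- c("I-II", "III-IV", "V", "VI", "VII", "VIII", "IX", "X")
  if (!label %in% labels_ok) {
    stop("unknown lamina label: ", label, call. = FALSE)
  }
  v <- as.matrix(as.data.frame(vertices))
  stopifnot(ncol(v) == 2, nrow(v) >= 3)
  dimnames(v) <- list(NULL, c("x", "y"))
  if (polygon_self_intersects(v)) {
    stop("ROI polygon is self-intersecting", call. = FALSE)
  }
  a <- polygon_area(v)
  if (a <= 0) stop("ROI polygon has non-positive area", call. = FALSE)
  structure(list(label = label, vertices = v, area_um2 = a),
            class = "lamina_roi")
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

seg_properly_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_edges <- function(v) {
  n <- nrow(v)
  lapply(seq_len(n), function(i) rbind(v[i, ], v[if (i == n) 1L else i + 1L, ]))
}

polygon_self_intersects <- function(v) {
  e <- polygon_edges(v)
  n <- length(e)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next # adjacent via closure
      if (seg_properly_intersect(e[[i]][1, ], e[[i]][2, ],
                                 e[[j]][1, ], e[[j]][2, ])) return(TRUE)
    }
  }
  FALSE
}

# even-odd point-in-polygon with on-boundary counted as inside
point_in_polygon <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  vapply(seq_along(px), function(k) {
    X <- px[k]; Y <- py[k]
    # boundary test
    on <- FALSE
    for (i in seq_len(n)) {
      cross <- (xn[i] - x[i]) * (Y - y[i]) - (yn[i] - y[i]) * (X - x[i])
      if (abs(cross) <= eps * max(1, abs(xn[i] - x[i]) + abs(yn[i] - y[i]))) {
        if (X >= min(x[i], xn[i]) - eps && X <= max(x[i], xn[i]) + eps &&
            Y >= min(y[i], yn[i]) - eps && Y <= max(y[i], yn[i]) + eps) {
          on <- TRUE; break
        }
      }
    }
    if (on) return(TRUE)
    inside <- FALSE
    for (i in seq_len(n)) {
      if ((y[i] > Y) != (yn[i] > Y)) {
        xint <- x[i] + (Y - y[i]) / (yn[i] - y[i]) * (xn[i] - x[i])
        if (X < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

polygons_overlap <- function(a, b) {
  ea <- polygon_edges(a$vertices); eb <- polygon_edges(b$vertices)
  for (i in seq_along(ea)) {
    for (j in seq_along(eb)) {
      if (seg_properly_intersect(ea[[i]][1, ], ea[[i]][2, ],
                                 eb[[j]][1, ], eb[[j]][2, ])) return(TRUE)
    }
  }
  # a vertex of one strictly interior to the other (boundary contact allowed)
  interior <- function(pt, v, eps = 1e-7) {
    # inside at four slightly perturbed positions => interior
    all(point_in_polygon(pt[1] + c(eps, -eps, 0, 0),
                         pt[2] + c(0, 0, eps, -eps), v))
  }
  any(apply(a$vertices, 1, interior, v = b$vertices)) ||
    any(apply(b$vertices, 1, interior, v = a$vertices))
}

assign_lamina_labels <- function(x_um, y_um, rois) {
  out <- rep(NA_character_, length(x_um))
  for (roi in rois) {
    hit <- is.na(out) & point_in_polygon(x_um, y_um, roi$vertices)
    out[hit] <- roi$label
  }
  out
}

#' Assign PSDs to laminar ROIs
#'
#' Membership is by centroid: a PSD belongs to the ROI whose polygon
#' contains its centroid under the even-odd rule, with points exactly on
#' the boundary counted as inside (and resolved to the first ROI in list
#' order when two ROIs share that boundary). PSDs outside every ROI get
#' lamina `NA`. Overlapping ROIs are a validation error naming the
#' offending pair.
#'
#' @param psds tibble with `x_um`, `y_um`.
#' @param rois list of [lamina_roi()].
#' @return `psds` with a `lamina` column.
#' @export
assign_lamina <- function(psds, rois) {
  if (length(rois) > 1L) {
    for (i in seq_len(length(rois) - 1L)) {
      for (j in seq(i + 1L, length(rois))) {
        if (polygons_overlap(rois[[i]], rois[[j]])) {
          stop(sprintf("ROIs '%s' and '%s' overlap", rois[[i]]$label,
                       rois[[j]]$label), call. = FALSE)
        }
      }
    }
  }
  psds$lamina <- assign_lamina_labels(psds$x_um, psds$y_um, rois)
  psds
}

#' Read / write lamina ROIs as JSON
#'
#' The on-disk format is a JSON array of `{label, vertices}` objects with
#' vertices in micrometres.
#'
#' @param rois list of [lamina_roi()].
#' @param path JSON path.
#' @export
write_rois <- function(rois, path) {
  payload <- lapply(rois, function(r) {
    list(label = r$label,
         vertices = as.data.frame(r$vertices))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
  lapply(seq_along(x), function(i) {
    item <- if (is.data.frame(x)) x[i, ] else x[[i]]
    lamina_roi(item$label, as.data.frame(item$vertices))
  })
}

#' Per-lamina mapping summary
#'
#' Computes the field-level and object-level metrics per lamina ROI:
#' whole-field mean raw intensity over the ROI, PSD density (count per
#' `density_unit_um2`, default per 100 um^2), mean PSD intensity, median
#' PSD size and mean integrated intensity, over PSDs whose centroid lies
#' in the polygon.
#'
#' @param psds PSD measurement tibble (needs `x_um`, `y_um`,
#'   `mean_intensity`, `integrated_intensity`, `area_um2`; a `lamina`
#'   column is used if present, else membership is recomputed).
#' @param roi a [lamina_roi()].
#' @param raw optional raw [channel_image()] for the field-intensity
#'   metric.
#' @param density_unit_um2 area unit for the density (default 100 um^2).
#' @return A one-row tibble of the lamina metrics.
#' @export
summarise_lamina <- function(psds, roi, raw = NULL, density_unit_um2 = 100) {
  inside <- if ("lamina" %in% names(psds) && !all(is.na(psds$lamina))) {
    !is.na(psds$lamina) & psds$lamina == roi$label
  } else {
    point_in_polygon(psds$x_um, psds$y_um, roi$vertices)
  }
  sel <- psds[inside, , drop = FALSE]
  n <- nrow(sel)
  field <- NA_real_
  if (!is.null(raw)) {
    s_um <- raw$pixel_size_nm / 1000
    cx <- (seq_len(ncol(raw$pixels)) - 0.5) * s_um
    cy <- (seq_len(nrow(raw$pixels)) - 0.5) * s_um
    # restrict to the ROI bounding box before the polygon test
    bx <- range(roi$vertices[, 1]); by <- range(roi$vertices[, 2])
    ci <- which(cx >= bx[1] & cx <= bx[2]); ri <- which(cy >= by[1] & cy <= by[2])
    if (length(ci) && length(ri)) {
      grid <- expand.grid(r = ri, c = ci)
      keep <- point_in_polygon(cx[grid$c], cy[grid$r], roi$vertices)
      if (any(keep)) {
        field <- mean(raw$pixels[cbind(grid$r[keep], grid$c[keep])])
      }
    }
  }
  tibble::tibble(
    lamina = roi$label, area_um2 = roi$area_um2, n_psds = n,
    field_intensity = field,
    psd_density = n / roi$area_um2 * density_unit_um2,
    mean_psd_intensity = if (n) mean(sel$mean_intensity) else NA_real_,
    median_psd_size_um2 = if (n) stats::median(sel$area_um2) else NA_real_,
    mean_integrated_intensity = if (n) mean(sel$integrated_intensity) else NA_real_)
}

#' Aggregate hemisection summaries to animals and groups
#'
#' The animal is the statistical unit: section-level values are averaged
#' across the (typically two) hemisections of each animal, then animal
#' values are carried to group mean and standard error.
#'
#' @param per_section tibble with a `section` column and one or more
#'   numeric value columns.
#' @param design tibble mapping every `section` to exactly one `animal`
#'   and `group`.
#' @return A list with `per_animal` (animal-level means, flagged when only
#'   one hemisection contributed) and `per_group` (group mean, SEM, n).
#' @export
aggregate_animals <- function(per_section, design) {
  if (!all(per_section$section %in% design$section)) {
    orphan <- setdiff(per_section$section, design$section)
    stop("sections missing from the design: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(design$section)) {
    stop("design maps a section to more than one animal", call. = FALSE)
  }
  value_cols <- setdiff(names(per_section), "section")
  joined <- dplyr::inner_join(per_section, design, by = "section")
  per_animal <- joined |>
    dplyr::group_by(.data$group, .data$animal) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_sections = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(single_section = .data$n_sections == 1L)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  per_group <- per_animal |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(value_cols),
                    list(mean = ~ mean(.x), sem = ~ sem(.x))),
      n_animals = dplyr::n(), .groups = "drop")
  list(per_animal = per_animal, per_group = per_group)
}

#' Pearson contingency chi-squared
#'
#' The Pearson statistic `sum((O - E)^2 / E)` with expected counts from
#' the table margins, `df = (r - 1)(c - 1)` and no continuity correction —
#' the test used for regional comparisons of per-PSD NC-count classes.
#'
#' @param table an `r x c` matrix (or object coercible to one) of counts.
#' @return A `contingency_chi2` object: `table`, `expected`, `chi2`, `df`,
#'   `p`.
#' @export
contingency_chi2 <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(!is.finite(m))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(m)
  chi2 <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(list(table = m, expected = expected, chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "contingency_chi2")
}

#' @export
print.contingency_chi2 <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: X2(%d) = %.4g, p = %.4g\n",
              x$df, x$chi2, x$p))
  print(x$table)
  invisible(x)
}

#' Tidy a contingency chi-squared result
#'
#' `tidy()` returns one row per cell with observed and expected counts and
#' the standardised Pearson residual; `glance()` returns the one-row test
#' summary.
#'
#' @param x a `contingency_chi2` object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.contingency_chi2 <- function(x, ...) {
  d <- as.data.frame(as.table(x$table))
  names(d) <- c("row", "col", "observed")
  d$expected <- as.vector(x$expected)
  d$residual <- (d$observed - d$expected) / sqrt(d$expected)
  tibble::as_tibble(d)
}

#' @rdname tidy.contingency_chi2
#' @export
glance.contingency_chi2 <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = x$df, p.value = x$p,
                 n = sum(x$table))
}
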