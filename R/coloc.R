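#' Object-overlap colocalization
#'
#' An object in `labels_a` is colocalized with `mask_b` when at least
#' `min_overlap_px` of its pixels fall on foreground of `mask_b` — the
#' "overlap by at least 1 pixel" rule. When the two inputs have different
#' pixel sizes the comparison is evaluated on the finer grid, upsampling
#' the coarser input by nearest neighbour so the pixel rule keeps its
#' native meaning at the resolution where it was defined; both inputs must
#' cover the same physical frame.
#'
#' @param labels_a a [label_image()] of candidate objects.
#' @param mask_b a [binary_mask()] (or [label_image()], treated as
#'   foreground `> 0`).
#' @param min_overlap_px minimum overlapping pixel count (default 1),
#'   counted on `labels_a`'s grid.
#' @return A tibble: `id`, `overlap_px`, `colocalized`.
#' @export
overlap_colocalize <- function(labels_a, mask_b, min_overlap_px = 1L) {
  stopifnot(inherits(labels_a, "label_image"))
  fg_b <- if (inherits(mask_b, "binary_mask")) mask_b$pixels else
    mask_b$pixels > 0L
  size_b <- if (inherits(mask_b, "binary_mask")) mask_b$pixel_size_nm else
    mask_b$pixel_size_nm
  ext_a <- physical_extent_um(labels_a)
  ext_b <- c(x = ncol(fg_b), y = nrow(fg_b)) * size_b / 1000
  if (any(abs(ext_a - ext_b) > max(labels_a$pixel_size_nm, size_b) / 1000)) {
    stop("inputs do not cover the same physical frame", call. = FALSE)
  }
  la <- labels_a$pixels
  if (abs(size_b - labels_a$pixel_size_nm) > 1e-9) {
    # resample mask_b onto labels_a's grid by nearest neighbour
    rr <- pmin(pmax(ceiling((seq_len(nrow(la)) - 0.5) *
                              labels_a$pixel_size_nm / size_b), 1L), nrow(fg_b))
    cc <- pmin(pmax(ceiling((seq_len(ncol(la)) - 0.5) *
                              labels_a$pixel_size_nm / size_b), 1L), ncol(fg_b))
    fg_b <- fg_b[rr, cc, drop = FALSE]
  }
  n <- labels_a$n
  if (n == 0L) {
    return(tibble::tibble(id = integer(), overlap_px = integer(),
                          colocalized = logical()))
  }
  idx <- which(la > 0L)
  ov <- tabulate(la[idx][fg_b[idx]], nbins = n)
  tibble::tibble(id = seq_len(n), overlap_px = as.integer(ov),
                 colocalized = ov >= min_overlap_px)
}

#' Four-way tripartite categorisation
#'
#' Maps per-PSD presynaptic and astrocytic colocalization flags to the
#' four categories: `psd_only` (neither), `psd_astro` (astro only),
#' `synapse` (presynaptic bouton only) and `tripartite` (both).
#'
#' @param vglut,astro logical vectors.
#' @return A factor with levels `psd_only`, `psd_astro`, `synapse`,
#'   `tripartite`.
#' @export
classify_category <- function(vglut, astro) {
  cls <- dplyr::case_when(vglut & astro ~ "tripartite",
                          vglut & !astro ~ "synapse",
                          !vglut & astro ~ "psd_astro",
                          TRUE ~ "psd_only")
  factor(cls, levels = c("psd_only", "psd_astro", "synapse", "tripartite"))
}

#' Nearest astrocytic neighbours of each PSD
#'
#' For every PSD centroid, the `k` smallest centre-centre Euclidean
#' distances to astro puncta (ascending, `NA`-padded when fewer than `k`
#' exist) plus the count of astro puncta within `radius_um` (closed
#' boundary: a punctum at exactly the radius is counted).
#'
#' @param psd_pts,astro_pts tibbles/data frames with `x_um`, `y_um` (and
#'   optionally `id`).
#' @param k neighbours retained (default 10).
#' @param radius_um counting radius (default 3).
#' @return A tibble: `psd_id`, `nn_distances_um` (list column of `k`
#'   ascending distances), `mean_nn_um`, `count_within_radius`, `padded`.
#' @export
nearest_neighbors <- function(psd_pts, astro_pts, k = 10L, radius_um = 3.0) {
  stopifnot(k >= 1L)
  ids <- psd_pts$id %||% seq_len(nrow(psd_pts))
  n_a <- nrow(astro_pts)
  rows <- purrr::map(seq_len(nrow(psd_pts)), function(i) {
    if (n_a == 0L) {
      d_sorted <- rep(NA_real_, k)
      return(tibble::tibble(psd_id = ids[i],
                            nn_distances_um = list(d_sorted),
                            mean_nn_um = NA_real_,
                            count_within_radius = 0L, padded = TRUE))
    }
    d <- sqrt((astro_pts$x_um - psd_pts$x_um[i])^2 +
                (astro_pts$y_um - psd_pts$y_um[i])^2)
    d_sorted <- sort(d)[seq_len(min(k, n_a))]
    padded <- length(d_sorted) < k
    if (padded) d_sorted <- c(d_sorted, rep(NA_real_, k - length(d_sorted)))
    tibble::tibble(psd_id = ids[i], nn_distances_um = list(d_sorted),
                   mean_nn_um = mean(d_sorted, na.rm = TRUE),
                   count_within_radius = sum(d <= radius_um),
                   padded = padded)
  })
  dplyr::bind_rows(rows)
}

object_boundary_px <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  fg <- lab > 0L
  pad <- function(shift_r, shift_c) {
    m <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + shift_r; cs <- seq_len(nc) + shift_c
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    m[ok_r, ok_c] <- fg[rs[ok_r], cs[ok_c]]
    m
  }
  interior <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  fg & !interior # 4-neighbour boundary; image-edge pixels are boundary
}

#' Edge-edge neighbour counts
#'
#' For each PSD, counts astro objects whose edge-edge distance is at most
#' `max_nm`. The edge-edge distance between two labelled objects is 0 when
#' their masks overlap on the common grid, otherwise the minimum distance
#' between the centres of their boundary pixels. Both label images must
#' share one grid (STED-resolution analysis).
#'
#' @param psd_labels,astro_labels [label_image()]s on the same grid.
#' @param max_nm distance limit (default 200, closed boundary).
#' @return A list with `per_psd` (tibble `psd_id`,
#'   `n_astro_within_max`) and `pairs` (tibble `astro_id`, `psd_id`,
#'   `distance_nm` of each astro object's nearest PSD).
#' @export
edge_edge_count <- function(psd_labels, astro_labels, max_nm = 200) {
  stopifnot(inherits(psd_labels, "label_image"),
            inherits(astro_labels, "label_image"),
            identical(dim(psd_labels$pixels), dim(astro_labels$pixels)))
  s_nm <- psd_labels$pixel_size_nm
  n_p <- psd_labels$n; n_a <- astro_labels$n
  per_psd <- tibble::tibble(psd_id = seq_len(n_p), n_astro_within_max = 0L)
  if (n_p == 0L || n_a == 0L) {
    return(list(per_psd = per_psd,
                pairs = tibble::tibble(astro_id = integer(), psd_id = integer(),
                                       distance_nm = numeric())))
  }
  bp <- object_boundary_px(psd_labels$pixels)
  ba <- object_boundary_px(astro_labels$pixels)
  coords <- function(sel, lab) {
    idx <- which(sel)
    nr <- nrow(lab)
    tibble::tibble(id = lab[idx],
                   r = ((idx - 1L) %% nr) + 1L,
                   c = ((idx - 1L) %/% nr) + 1L)
  }
  pb <- coords(bp, psd_labels$pixels)
  ab <- coords(ba, astro_labels$pixels)
  overlap <- overlap_colocalize(astro_labels, psd_labels, min_overlap_px = 1L)
  pairs <- purrr::map(seq_len(n_a), function(ai) {
    a <- ab[ab$id == ai, ]
    if (overlap$colocalized[ai]) {
      # overlapping: find which PSD(s) it touches
      idx <- which(astro_labels$pixels == ai & psd_labels$pixels > 0L)
      hit <- sort(unique(psd_labels$pixels[idx]))
      return(tibble::tibble(astro_id = ai, psd_id = hit[1], distance_nm = 0))
    }
    best_d2 <- Inf; best_p <- NA_integer_
    for (pi in seq_len(n_p)) {
      p <- pb[pb$id == pi, ]
      d2 <- min(outer(a$r, p$r, "-")^2 + outer(a$c, p$c, "-")^2)
      if (d2 < best_d2) { best_d2 <- d2; best_p <- pi }
    }
    tibble::tibble(astro_id = ai, psd_id = best_p,
                   distance_nm = sqrt(best_d2) * s_nm)
  }) |> dplyr::bind_rows()
  counts <- pairs |>
    dplyr::filter(.data$distance_nm <= max_nm) |>
    dplyr::count(.data$psd_id, name = "n")
  per_psd$n_astro_within_max[counts$psd_id] <- counts$n
  list(per_psd = per_psd, pairs = pairs)
}

#' 180-degree rotated spatial null
#'
#' Rotates one channel half a turn about the frame centre, preserving
#' every object-level statistic (count, size, intensity) while scrambling
#' its spatial relationship to the other channels — the rotated-control
#' null for colocalization statistics. Masks and label/channel images
#' rotate pixelwise, `(r, c) -> (H + 1 - r, W + 1 - c)`; point tables
#' rotate in physical coordinates, `(x, y) -> (W - x, H - y)`, given the
#' frame extent.
#'
#' @param x a [binary_mask()], [label_image()], [channel_image()], or a
#'   data frame with `x_um`, `y_um`.
#' @param field_um physical frame `c(x, y)` in micrometres; required for
#'   point tables, ignored for images (their own frame is used).
#' @return The same type as `x`, rotated.
#' @export
rotated_control <- function(x, field_um = NULL) {
  rot_mat <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
  if (inherits(x, "binary_mask")) {
    out <- x; out$pixels <- rot_mat(x$pixels)
    out$provenance$rotated <- TRUE
    return(out)
  }
  if (inherits(x, "label_image")) {
    return(label_image(rot_mat(x$pixels), x$pixel_size_nm))
  }
  if (inherits(x, "channel_image")) {
    return(channel_image(rot_mat(x$pixels), x$pixel_size_nm, x$modality,
                         x$label))
  }
  if (is.data.frame(x)) {
    if (is.null(field_um)) {
      stop("`field_um` is required to rotate a point table", call. = FALSE)
    }
    out <- x
    out$x_um <- field_um[1] - x$x_um
    out$y_um <- field_um[2] - x$y_um
    return(out)
  }
  stop("cannot rotate object of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' Summarise true vs rotated-control neighbour statistics
#'
#' Pairs the neighbour tables of the true and rotated arms computed with
#' identical parameters and reports the per-arm means of the
#' count-within-radius and mean-10-NN distance, their differences, and the
#' effect direction.
#'
#' @param true_tables,rotated_tables outputs of [nearest_neighbors()] over
#'   the same PSD set.
#' @return A one-row tibble: `n_psd`, `mean_count_true`,
#'   `mean_count_rotated`, `count_diff`, `mean_nn_true`,
#'   `mean_nn_rotated`, `nn_diff`, `direction`.
#' @export
null_comparison <- function(true_tables, rotated_tables) {
  if (nrow(true_tables) != nrow(rotated_tables) ||
      !identical(sort(true_tables$psd_id), sort(rotated_tables$psd_id))) {
    stop("true and rotated tables cover different PSD sets", call. = FALSE)
  }
  mc_t <- mean(true_tables$count_within_radius)
  mc_r <- mean(rotated_tables$count_within_radius)
  nn_t <- mean(true_tables$mean_nn_um, na.rm = TRUE)
  nn_r <- mean(rotated_tables$mean_nn_um, na.rm = TRUE)
  tibble::tibble(
    n_psd = nrow(true_tables),
    mean_count_true = mc_t, mean_count_rotated = mc_r,
    count_diff = mc_t - mc_r,
    mean_nn_true = nn_t, mean_nn_rotated = nn_r,
    nn_diff = nn_t - nn_r,
    direction = dplyr::case_when(mc_t > mc_r ~ "true > rotated",
                                 mc_t < mc_r ~ "true < rotated",
                                 TRUE ~ "equal"))
}
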