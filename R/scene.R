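#' Scene generation parameters
#'
#' Defaults describe a ventral-horn-like field: PSDs composed of 1-3
#' nanoclusters (NCs) with a 47% two-plus-NC fraction, elliptical NCs with
#' lognormal axis lengths around 92 x 185 nm full width at half maximum
#' (FWHM), 45% of PSDs apposed by a presynaptic bouton, 56% of those
#' synapses additionally contacted by a perisynaptic astrocytic nanodomain
#' (median diameter 119 nm), and two bouton classes whose substructure
#' diameters centre on 90 nm (VGLUT2) and 272 nm (VGLUT1). Densities and
#' separations are chosen so that objects are optically resolvable at the
#' rendered resolutions; see the methods vignette for the rationale behind
#' each free parameter.
#'
#' @param field_um field extent `c(x, y)` in micrometres.
#' @param margin_um no objects are centred closer than this to the field
#'   edge (keeps rendered mass inside the frame).
#' @param psd_density_um2 PSDs per square micrometre.
#' @param min_psd_sep_um minimum PSD centre-centre separation.
#' @param nc_count_probs probability of 1, 2, ... NCs per PSD.
#' @param nc_disc_radius_nm NC centres are drawn within this radius of the
#'   PSD centre.
#' @param nc_min_sep_nm minimum NC centre-centre separation within a PSD
#'   (keeps multi-NC truth resolvable).
#' @param psd_diffuse_frac fraction of extra PSD95 signal carried by a
#'   diffuse (non-nanoclustered) scaffold pool, relative to the PSD's
#'   total NC amplitude; keeps the confocal punctum contiguous, as in
#'   tissue where PSD95 occupies the whole PSD.
#' @param psd_diffuse_sigma_nm Gaussian sigma of that diffuse pool.
#' @param fwhm_long_meanlog,fwhm_long_sdlog,fwhm_short_meanlog,fwhm_short_sdlog
#'   lognormal parameters of the NC long/short FWHM axes in nm.
#' @param nc_amp_meanlog,nc_amp_sdlog lognormal NC amplitude (total photons).
#' @param bouton_frac fraction of PSDs apposed by a presynaptic bouton.
#' @param bouton_mix named probabilities for classes `vglut1`, `vglut2`.
#' @param tripartite_frac probability that a synapse (PSD with bouton) is
#'   also contacted by an astrocytic nanodomain.
#' @param astro_nonsyn_frac probability that a bouton-less PSD is contacted
#'   by an astrocytic nanodomain.
#' @param decoy_astro_density_um2 density of unlinked astrocytic puncta.
#' @param vglut1_sub_count,vglut2_sub_count integer range of substructures
#'   per bouton.
#' @param vglut1_diam_meanlog,vglut1_diam_sdlog,vglut2_diam_meanlog,vglut2_diam_sdlog
#'   lognormal substructure diameters (nm).
#' @param bouton_amp_meanlog,bouton_amp_sdlog,astro_amp_meanlog,astro_amp_sdlog
#'   lognormal amplitudes (photons).
#' @param astro_diam_meanlog,astro_diam_sdlog lognormal astro diameters (nm).
#' @param edge_gap_range_nm edge-edge gap (uniform) between a PSD and its
#'   linked bouton/astro domain.
#' @param background_rate constant background, photons per pixel.
#' @param rois optional list of lamina ROIs ([lamina_roi()]) used to label
#'   PSDs at generation time.
#' @return A `scene_params` list.
#' @export
scene_params <- function(field_um = c(40, 40),
                         margin_um = 1.5,
                         psd_density_um2 = 0.12,
                         min_psd_sep_um = 1.2,
                         nc_count_probs = c(0.53, 0.32, 0.15),
                         nc_disc_radius_nm = 230,
                         nc_min_sep_nm = 350,
                         psd_diffuse_frac = 0.25,
                         psd_diffuse_sigma_nm = 150,
                         fwhm_long_meanlog = log(185), fwhm_long_sdlog = 0.25,
                         fwhm_short_meanlog = log(92), fwhm_short_sdlog = 0.20,
                         nc_amp_meanlog = log(8000), nc_amp_sdlog = 0.15,
                         bouton_frac = 0.45,
                         bouton_mix = c(vglut1 = 0.5, vglut2 = 0.5),
                         tripartite_frac = 0.56,
                         astro_nonsyn_frac = 0.25,
                         decoy_astro_density_um2 = 0.05,
                         vglut1_sub_count = c(1L, 2L),
                         vglut2_sub_count = c(2L, 4L),
                         vglut1_diam_meanlog = log(272), vglut1_diam_sdlog = 0.35,
                         vglut2_diam_meanlog = log(90), vglut2_diam_sdlog = 0.25,
                         bouton_amp_meanlog = log(8000), bouton_amp_sdlog = 0.15,
                         astro_diam_meanlog = log(119), astro_diam_sdlog = 0.20,
                         astro_amp_meanlog = log(6000), astro_amp_sdlog = 0.15,
                         edge_gap_range_nm = c(0, 100),
                         background_rate = 5,
                         rois = NULL) {
  p <- as.list(environment())
  if (any(c(p$psd_density_um2, p$decoy_astro_density_um2) < 0)) {
    stop("densities must be >= 0", call. = FALSE)
  }
  probs <- c(p$bouton_frac, p$tripartite_frac, p$astro_nonsyn_frac,
             p$nc_count_probs, p$bouton_mix)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p$nc_count_probs) - 1) > 1e-8) {
    stop("`nc_count_probs` must sum to 1", call. = FALSE)
  }
  structure(p, class = "scene_params")
}

#' Ground-truth scene container
#'
#' Holds per-object truth sufficient to recompute every downstream summary
#' (NC count per PSD, tripartite flag, bouton class) without touching
#' images. Usually produced by [generate_scene()]; the constructor is
#' exported so that fully controlled scenes can be built in tests and
#' examples.
#'
#' @param psds,ncs,boutons,bouton_subs,astros tibbles; see
#'   [generate_scene()] for their columns.
#' @param field_um field extent `c(x, y)` in micrometres.
#' @param background_rate photons per pixel.
#' @param params the generating [scene_params()] (or `NULL` for manual
#'   scenes).
#' @param seed the generating seed (or `NA`).
#' @return A `ground_truth_scene` object.
#' @export
ground_truth_scene <- function(psds = empty_psds(), ncs = empty_ncs(),
                               boutons = empty_boutons(),
                               bouton_subs = empty_bouton_subs(),
                               astros = empty_astros(),
                               field_um = c(20, 20), background_rate = 5,
                               params = NULL, seed = NA_integer_) {
  if (nrow(psds) && is.null(psds$diffuse_amplitude)) {
    psds$diffuse_amplitude <- 0
    psds$diffuse_sigma_nm <- 0
  }
  scene <- structure(
    list(psds = psds, ncs = ncs, boutons = boutons,
         bouton_subs = bouton_subs, astros = astros,
         field_um = field_um, background_rate = background_rate,
         params = params, seed = seed),
    class = "ground_truth_scene")
  validate_scene(scene)
  scene
}

empty_psds <- function() {
  tibble::tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                 lamina = character(), bouton_id = integer(),
                 astro_id = integer(), diffuse_amplitude = numeric(),
                 diffuse_sigma_nm = numeric())
}
empty_ncs <- function() {
  tibble::tibble(id = integer(), psd_id = integer(), x_um = numeric(),
                 y_um = numeric(), fwhm_long_nm = numeric(),
                 fwhm_short_nm = numeric(), theta = numeric(),
                 amplitude = numeric())
}
empty_boutons <- function() {
  tibble::tibble(id = integer(), psd_id = integer(), class = character(),
                 x_um = numeric(), y_um = numeric())
}
empty_bouton_subs <- function() {
  tibble::tibble(bouton_id = integer(), x_um = numeric(), y_um = numeric(),
                 diameter_nm = numeric(), amplitude = numeric())
}
empty_astros <- function() {
  tibble::tibble(id = integer(), psd_id = integer(), x_um = numeric(),
                 y_um = numeric(), diameter_nm = numeric(),
                 amplitude = numeric())
}

validate_scene <- function(scene) {
  with(scene, {
    in_field <- function(x, y) {
      all(x >= 0 & x <= field_um[1] & y >= 0 & y <= field_um[2])
    }
    stopifnot(in_field(psds$x_um, psds$y_um), in_field(ncs$x_um, ncs$y_um),
              in_field(astros$x_um, astros$y_um))
    stopifnot(all(ncs$fwhm_short_nm <= ncs$fwhm_long_nm + 1e-9))
    stopifnot(all(stats::na.omit(ncs$psd_id) %in% psds$id))
    stopifnot(all(stats::na.omit(psds$bouton_id) %in% boutons$id))
    stopifnot(all(stats::na.omit(psds$astro_id) %in% astros$id))
    stopifnot(all(bouton_subs$bouton_id %in% boutons$id))
  })
  invisible(scene)
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("<ground_truth_scene> %.3g x %.3g um, seed %s\n",
              x$field_um[1], x$field_um[2], format(x$seed)))
  cat(sprintf("  %d PSDs, %d NCs, %d boutons, %d astro domains\n",
              nrow(x$psds), nrow(x$ncs), nrow(x$boutons), nrow(x$astros)))
  invisible(x)
}

# dart-throwing placement with a hard-core minimum separation
place_hardcore <- function(n, lo, hi, min_sep, max_attempts = 500L) {
  if (min_sep <= 0) {
    return(cbind(x = stats::runif(n, lo[1], hi[1]),
                 y = stats::runif(n, lo[2], hi[2])))
  }
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- stats::runif(1, lo[1], hi[1]); y <- stats::runif(1, lo[2], hi[2])
      if (length(xs) == 0L || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed) {
      warning(sprintf("placed only %d of %d objects at the requested separation",
                      length(xs), n))
      break
    }
  }
  cbind(x = xs, y = ys)
}

# NC offsets (nm) within a disc, with a hard-core minimum separation.
# Batched tuple rejection: draw `batch` candidate k-tuples uniformly in the
# disc and keep the first whose pairwise separations all clear min_sep. For
# packings too tight for rejection (three points near the disc's capacity)
# it falls back to a randomly rotated regular k-gon at a feasible
# circumradius, and errors only if no such radius exists.
place_nc_offsets <- function(k, disc_r, min_sep, batch = 400L) {
  if (k == 1L) {
    r <- disc_r * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
    return(cbind(r * cos(th), r * sin(th)))
  }
  r <- disc_r * sqrt(stats::runif(batch * k))
  th <- stats::runif(batch * k, 0, 2 * pi)
  X <- matrix(r * cos(th), batch, k)
  Y <- matrix(r * sin(th), batch, k)
  ok <- rep(TRUE, batch)
  for (a in seq_len(k - 1L)) {
    for (b in seq(a + 1L, k)) {
      ok <- ok & ((X[, a] - X[, b])^2 + (Y[, a] - Y[, b])^2 >= min_sep^2)
    }
  }
  j <- which(ok)[1]
  if (!is.na(j)) return(cbind(X[j, ], Y[j, ]))
  rc_min <- min_sep / (2 * sin(pi / k))
  if (rc_min > disc_r) {
    stop("cannot place substructures at the requested minimum separation",
         call. = FALSE)
  }
  rc <- stats::runif(1, rc_min, disc_r)
  ang <- stats::runif(1, 0, 2 * pi) + 2 * pi * (seq_len(k) - 1) / k
  cbind(rc * cos(ang), rc * sin(ang))
}

#' Generate a ground-truth synaptic scene
#'
#' Draws PSD positions by hard-core dart throwing, gives each PSD 1+
#' elliptical NCs, attaches presynaptic boutons and perisynaptic astrocytic
#' nanodomains by independent Bernoulli draws at the configured fractions
#' (with an edge-edge gap drawn uniformly from `edge_gap_range_nm`), and
#' scatters unlinked decoy astro puncta. Reproducible: the same
#' `(params, seed)` yields an identical scene.
#'
#' @param params a [scene_params()].
#' @param seed integer seed.
#' @return A [ground_truth_scene()] whose tibbles record every placement,
#'   shape, amplitude and association link.
#' @export
generate_scene <- function(params = scene_params(), seed) {
  stopifnot(inherits(params, "scene_params"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::with_seed(as.integer(seed), generate_scene_impl(params, seed))
}

generate_scene_impl <- function(p, seed) {
  usable <- pmax(p$field_um - 2 * p$margin_um, 0)
  n_psd <- round(p$psd_density_um2 * prod(usable))
  if (n_psd > 0) {
    xy <- place_hardcore(n_psd, lo = rep(p$margin_um, 2),
                         hi = p$field_um - p$margin_um, min_sep = p$min_psd_sep_um)
    n_psd <- nrow(xy)
  } else xy <- cbind(x = numeric(0), y = numeric(0))

  # accumulate plain columns; tibbles are assembled once at the end
  nc_rows <- vector("list", n_psd)
  bout_rows <- vector("list", n_psd); bsub_rows <- vector("list", n_psd)
  astro_rows <- vector("list", n_psd)
  psd_bouton <- rep(NA_integer_, n_psd); psd_astro <- rep(NA_integer_, n_psd)
  psd_diffuse <- numeric(n_psd)
  nc_id <- 0L; b_id <- 0L; a_id <- 0L

  nc_counts <- if (n_psd > 0)
    sample.int(length(p$nc_count_probs), n_psd, replace = TRUE,
               prob = p$nc_count_probs) else integer(0)

  for (i in seq_len(n_psd)) {
    k <- nc_counts[i]
    off <- place_nc_offsets(k, p$nc_disc_radius_nm, p$nc_min_sep_nm)
    fl <- stats::rlnorm(k, p$fwhm_long_meanlog, p$fwhm_long_sdlog)
    fs <- stats::rlnorm(k, p$fwhm_short_meanlog, p$fwhm_short_sdlog)
    swap <- fs > fl
    tmp <- fl[swap]; fl[swap] <- fs[swap]; fs[swap] <- tmp
    amp <- stats::rlnorm(k, p$nc_amp_meanlog, p$nc_amp_sdlog)
    th <- stats::runif(k, 0, pi)
    nc_rows[[i]] <- list(id = nc_id + seq_len(k), psd_id = rep(i, k),
                         x_um = unname(xy[i, 1] + off[, 1] / 1000),
                         y_um = unname(xy[i, 2] + off[, 2] / 1000),
                         fwhm_long_nm = fl, fwhm_short_nm = fs,
                         theta = th, amplitude = amp)
    nc_id <- nc_id + k
    # directional PSD extent (nm): how far the NC envelope reaches from the
    # PSD centre along a unit direction; partners attach at an edge gap in
    # their own direction, so contact geometry is tight regardless of where
    # the NCs sit
    psd_extent <- function(ang) {
      max(off[, 1] * cos(ang) + off[, 2] * sin(ang) + fl / 2)
    }

    has_bouton <- stats::runif(1) < p$bouton_frac
    if (has_bouton) {
      b_id <- b_id + 1L
      cls <- sample(names(p$bouton_mix), 1L, prob = p$bouton_mix)
      nsub_rng <- if (cls == "vglut1") p$vglut1_sub_count else p$vglut2_sub_count
      nsub <- sample(seq(nsub_rng[1], nsub_rng[2]), 1L)
      dml <- if (cls == "vglut1") p$vglut1_diam_meanlog else p$vglut2_diam_meanlog
      dsd <- if (cls == "vglut1") p$vglut1_diam_sdlog else p$vglut2_diam_sdlog
      d <- stats::rlnorm(nsub, dml, dsd)
      samp <- stats::rlnorm(nsub, p$bouton_amp_meanlog, p$bouton_amp_sdlog)
      soff <- place_nc_offsets(nsub, disc_r = max(d) * 0.8 + 40,
                               min_sep = stats::median(d) * 0.8)
      gap <- stats::runif(1, p$edge_gap_range_nm[1], p$edge_gap_range_nm[2])
      ang <- stats::runif(1, 0, 2 * pi)
      # bouton extent back towards the PSD, so the facing edges set the gap
      b_r <- max(-(soff[, 1] * cos(ang) + soff[, 2] * sin(ang)) + d / 2)
      dist_nm <- psd_extent(ang) + gap + b_r
      bx <- xy[i, 1] + dist_nm * cos(ang) / 1000
      by <- xy[i, 2] + dist_nm * sin(ang) / 1000
      bx <- min(max(bx, 0), p$field_um[1]); by <- min(max(by, 0), p$field_um[2])
      bout_rows[[i]] <- list(id = b_id, psd_id = i, class = cls,
                             x_um = bx, y_um = by)
      bsub_rows[[i]] <- list(bouton_id = rep(b_id, nsub),
                             x_um = bx + soff[, 1] / 1000,
                             y_um = by + soff[, 2] / 1000,
                             diameter_nm = d, amplitude = samp)
      psd_bouton[i] <- b_id
    }
    p_astro <- if (has_bouton) p$tripartite_frac else p$astro_nonsyn_frac
    if (stats::runif(1) < p_astro) {
      a_id <- a_id + 1L
      d <- stats::rlnorm(1, p$astro_diam_meanlog, p$astro_diam_sdlog)
      gap <- stats::runif(1, p$edge_gap_range_nm[1], p$edge_gap_range_nm[2])
      ang <- stats::runif(1, 0, 2 * pi)
      dist_nm <- psd_extent(ang) + gap + d / 2
      ax <- min(max(xy[i, 1] + dist_nm * cos(ang) / 1000, 0), p$field_um[1])
      ay <- min(max(xy[i, 2] + dist_nm * sin(ang) / 1000, 0), p$field_um[2])
      astro_rows[[i]] <- list(
        id = a_id, psd_id = i, x_um = ax, y_um = ay, diameter_nm = d,
        amplitude = stats::rlnorm(1, p$astro_amp_meanlog, p$astro_amp_sdlog))
      psd_astro[i] <- a_id
    }
    psd_diffuse[i] <- p$psd_diffuse_frac * sum(amp)
  }
  col_bind <- function(rows, proto) {
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(proto)
    out <- lapply(names(proto), function(nm) {
      vals <- unlist(lapply(rows, `[[`, nm), use.names = FALSE)
      if (is.integer(proto[[nm]])) as.integer(vals) else vals
    })
    names(out) <- names(proto)
    tibble::as_tibble(out)
  }
  psds <- if (n_psd > 0) tibble::tibble(
    id = seq_len(n_psd), x_um = unname(xy[, 1]), y_um = unname(xy[, 2]),
    lamina = NA_character_, bouton_id = psd_bouton, astro_id = psd_astro,
    diffuse_amplitude = psd_diffuse,
    diffuse_sigma_nm = p$psd_diffuse_sigma_nm) else empty_psds()
  ncs <- col_bind(nc_rows, empty_ncs())
  boutons <- col_bind(bout_rows, empty_boutons())
  bsubs <- col_bind(bsub_rows, empty_bouton_subs())
  astros <- col_bind(astro_rows, empty_astros())

  n_decoy <- round(p$decoy_astro_density_um2 * prod(p$field_um))
  if (n_decoy > 0) {
    astros <- dplyr::bind_rows(astros, tibble::tibble(
      id = a_id + seq_len(n_decoy), psd_id = NA_integer_,
      x_um = stats::runif(n_decoy, 0, p$field_um[1]),
      y_um = stats::runif(n_decoy, 0, p$field_um[2]),
      diameter_nm = stats::rlnorm(n_decoy, p$astro_diam_meanlog,
                                  p$astro_diam_sdlog),
      amplitude = stats::rlnorm(n_decoy, p$astro_amp_meanlog,
                                p$astro_amp_sdlog)))
  }
  if (!is.null(p$rois) && nrow(psds) > 0) {
    psds$lamina <- assign_lamina_labels(psds$x_um, psds$y_um, p$rois)
  }
  ground_truth_scene(psds, ncs, boutons, bsubs, astros,
                     field_um = p$field_um, background_rate = p$background_rate,
                     params = p, seed = as.integer(seed))
}

#' Per-PSD ground-truth summary
#'
#' One row per PSD with the NC count/class, bouton class and tripartite
#' flag, recomputed purely from the scene's bookkeeping. This is the oracle
#' that parameter-recovery tests compare pipeline output against.
#'
#' @param scene a [ground_truth_scene()].
#' @return A tibble: `psd_id`, `x_um`, `y_um`, `lamina`, `nc_count`,
#'   `nc_class`, `bouton_class`, `has_vglut`, `has_astro`, `category`.
#' @export
truth_summary <- function(scene) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  counts <- scene$ncs |>
    dplyr::filter(!is.na(.data$psd_id)) |>
    dplyr::count(.data$psd_id, name = "nc_count")
  out <- scene$psds |>
    dplyr::left_join(counts, by = c(id = "psd_id")) |>
    dplyr::mutate(nc_count = dplyr::coalesce(.data$nc_count, 0L)) |>
    dplyr::left_join(dplyr::select(scene$boutons, "id", bouton_class = "class"),
                     by = c(bouton_id = "id")) |>
    dplyr::mutate(
      bouton_class = dplyr::coalesce(.data$bouton_class, "none"),
      has_vglut = .data$bouton_class != "none",
      has_astro = !is.na(.data$astro_id),
      nc_class = classify_psd(.data$nc_count),
      category = classify_category(.data$has_vglut, .data$has_astro)) |>
    dplyr::select("id", "x_um", "y_um", "lamina", "nc_count", "nc_class",
                  "bouton_class", "has_vglut", "has_astro", "category") |>
    dplyr::rename(psd_id = "id")
  out
}

#' Export / import a scene as JSON
#'
#' @param scene a [ground_truth_scene()].
#' @param path JSON file path.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  payload <- list(field_um = scene$field_um,
                  background_rate = scene$background_rate,
                  seed = scene$seed,
                  psds = scene$psds, ncs = scene$ncs, boutons = scene$boutons,
                  bouton_subs = scene$bouton_subs, astros = scene$astros)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tb <- function(df, proto) {
    if (is.null(df) || length(df) == 0L || nrow(as.data.frame(df)) == 0L)
      return(proto)
    out <- tibble::as_tibble(df)
    for (nm in names(proto)) {
      if (!nm %in% names(out)) out[[nm]] <- proto[[nm]][NA_integer_][0]
      mode_target <- class(proto[[nm]])[1]
      out[[nm]] <- switch(mode_target,
                          integer = as.integer(out[[nm]]),
                          numeric = as.numeric(out[[nm]]),
                          character = as.character(out[[nm]]),
                          out[[nm]])
    }
    out[names(proto)]
  }
  ground_truth_scene(
    psds = as_tb(x$psds, empty_psds()), ncs = as_tb(x$ncs, empty_ncs()),
    boutons = as_tb(x$boutons, empty_boutons()),
    bouton_subs = as_tb(x$bouton_subs, empty_bouton_subs()),
    astros = as_tb(x$astros, empty_astros()),
    field_um = as.numeric(x$field_um),
    background_rate = x$background_rate,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed))
}
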