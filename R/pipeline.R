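#' Match detected objects to ground-truth placements
#'
#' Greedy one-to-one matching by ascending centre distance: the closest
#' (truth, detection) pairs within `max_dist_um` are matched first.
#' Precision and recall summarise the match.
#'
#' @param truth_pts,detected_pts tibbles with `x_um`, `y_um`.
#' @param max_dist_um maximum centre distance for a valid match.
#' @return A list: `matches` (tibble `truth_idx`, `det_idx`,
#'   `dist_um`), `recall`, `precision`, `n_truth`, `n_detected`.
#' @export
match_detections <- function(truth_pts, detected_pts, max_dist_um = 0.5) {
  nt <- nrow(truth_pts); nd <- nrow(detected_pts)
  if (nt == 0L || nd == 0L) {
    return(list(matches = tibble::tibble(truth_idx = integer(),
                                         det_idx = integer(),
                                         dist_um = numeric()),
                recall = if (nt == 0L) NA_real_ else 0,
                precision = if (nd == 0L) NA_real_ else 0,
                n_truth = nt, n_detected = nd))
  }
  d <- sqrt(outer(truth_pts$x_um, detected_pts$x_um, "-")^2 +
              outer(truth_pts$y_um, detected_pts$y_um, "-")^2)
  cand <- which(d <= max_dist_um, arr.ind = TRUE)
  ord <- order(d[cand])
  used_t <- logical(nt); used_d <- logical(nd)
  out <- list()
  for (k in ord) {
    ti <- cand[k, 1]; di <- cand[k, 2]
    if (used_t[ti] || used_d[di]) next
    used_t[ti] <- TRUE; used_d[di] <- TRUE
    out[[length(out) + 1L]] <- tibble::tibble(truth_idx = ti, det_idx = di,
                                              dist_um = d[ti, di])
  }
  matches <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(truth_idx = integer(), det_idx = integer(),
                   dist_um = numeric())
  list(matches = matches, recall = nrow(matches) / nt,
       precision = nrow(matches) / nd, n_truth = nt, n_detected = nd)
}

#' Run the full simulate-segment-classify pipeline
#'
#' Generates (or accepts) a ground-truth scene, renders the channels,
#' and runs both experiment arms of the analysis:
#'
#' * the mapping arm: high-resolution PSD95, VGLUT (presynaptic) and astro
#'   channels are segmented with the punctate protocol, PSDs are flagged
#'   by 1-pixel overlap against each marker mask and categorised into
#'   `psd_only` / `psd_astro` / `synapse` / `tripartite`; the tripartite
#'   fraction is reported among synapses (VGLUT-apposed PSDs) and among
#'   all PSDs;
#' * the nanostructure arm: a confocal and a STED PSD95 render are
#'   segmented, STED NCs (8 px minimum) are assigned to their parent
#'   confocal PSDs, and PSDs are classified by NC count; the 2+NC
#'   fraction is reported over PSDs with at least one NC (and over all
#'   PSDs).
#'
#' Deterministic given `(config, seed)`: channel noise seeds are derived
#' from `seed` by fixed offsets.
#'
#' @param config either a [scene_params()] object, a named list with
#'   optional entries `scene` (arguments to [scene_params()]), `pipeline`
#'   (arguments to [pipeline_config()]), `do_mapping`, `do_nanostruct`,
#'   or a path to a YAML file with that structure.
#' @param seed integer master seed.
#' @param rois optional list of [lamina_roi()] for laminar mapping.
#' @param outdir optional directory; when given, object tables are written
#'   as CSV, masks as TIFF and a JSON run record echoing every constant.
#' @return A list with the scene, truth summary, per-arm tables and the
#'   headline fractions (see the README worked example).
#' @export
run_pipeline <- function(config = list(), seed, rois = NULL, outdir = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "scene_params")) config <- list(scene_params = config)
  sp <- config$scene_params %||% do.call(scene_params, config$scene %||% list())
  cfg <- do.call(pipeline_config, config$pipeline %||% list())
  do_mapping <- config$do_mapping %||% TRUE
  do_nano <- config$do_nanostruct %||% TRUE
  seed <- as.integer(seed)

  scene <- generate_scene(sp, seed)
  truth <- truth_summary(scene)
  out <- list(scene = scene, truth = truth, config = cfg, seed = seed)

  if (do_mapping) {
    spec_hr <- render_spec("highres")
    img_psd <- render_channel(scene, "psd95", spec_hr, seed = seed + 11L)
    img_v1 <- render_channel(scene, "vglut1", spec_hr, seed = seed + 12L)
    img_v2 <- render_channel(scene, "vglut2", spec_hr, seed = seed + 13L)
    img_as <- render_channel(scene, "astro", spec_hr, seed = seed + 14L)
    seg_psd <- segment_channel(img_psd, cfg, "punctate")
    seg_v1 <- segment_channel(img_v1, cfg, "punctate")
    seg_v2 <- segment_channel(img_v2, cfg, "punctate")
    seg_as <- segment_channel(img_as, cfg, "punctate")
    fl_v1 <- overlap_colocalize(seg_psd$labels, seg_v1$mask, cfg$overlap_min_px)
    fl_v2 <- overlap_colocalize(seg_psd$labels, seg_v2$mask, cfg$overlap_min_px)
    fl_as <- overlap_colocalize(seg_psd$labels, seg_as$mask, cfg$overlap_min_px)
    psd_table <- seg_psd$objects |>
      dplyr::mutate(vglut1 = fl_v1$colocalized, vglut2 = fl_v2$colocalized,
                    astro = fl_as$colocalized,
                    has_vglut = .data$vglut1 | .data$vglut2,
                    category = classify_category(.data$has_vglut, .data$astro))
    if (!is.null(rois)) psd_table <- assign_lamina(psd_table, rois)
    n_syn <- sum(psd_table$category %in% c("synapse", "tripartite"))
    out$mapping <- list(
      images = list(psd95 = img_psd, vglut1 = img_v1, vglut2 = img_v2,
                    astro = img_as),
      segmentations = list(psd95 = seg_psd, vglut1 = seg_v1, vglut2 = seg_v2,
                           astro = seg_as),
      psd_table = psd_table,
      category_counts = dplyr::count(psd_table, .data$category,
                                     .drop = FALSE),
      tripartite_fraction_of_synapses =
        if (n_syn) sum(psd_table$category == "tripartite") / n_syn else NA_real_,
      tripartite_fraction_of_psds =
        if (nrow(psd_table)) mean(psd_table$category == "tripartite") else NA_real_)
  }

  if (do_nano) {
    spec_cf <- render_spec("confocal")
    spec_st <- render_spec("sted")
    img_cf <- render_channel(scene, "psd95", spec_cf, seed = seed + 21L)
    img_st <- render_channel(scene, "psd95", spec_st, seed = seed + 22L)
    seg_cf <- segment_channel(img_cf, cfg, "punctate")
    seg_st <- segment_channel(img_st, cfg, "punctate",
                              min_px = cfg$min_particle_px)
    assignment <- assign_ncs_to_psds(seg_cf$labels, seg_st$labels)
    nc_table <- psd_nc_table(assignment, seg_cf$objects)
    with_nc <- nc_table[nc_table$nc_count > 0L, ]
    out$nanostruct <- list(
      images = list(confocal = img_cf, sted = img_st),
      segmentations = list(confocal = seg_cf, sted = seg_st),
      assignment = assignment, nc_table = nc_table,
      nc_class_counts = dplyr::count(nc_table, .data$nc_class, .drop = FALSE),
      two_plus_fraction =
        if (nrow(with_nc)) mean(with_nc$nc_count >= 2L) else NA_real_,
      two_plus_fraction_all_psds =
        if (nrow(nc_table)) mean(nc_table$nc_count >= 2L) else NA_real_)
  }

  if (!is.null(outdir)) write_run_record(out, outdir, sp, cfg)
  out
}

write_run_record <- function(out, outdir, sp, cfg) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$truth, file.path(outdir, "truth_summary.csv"),
                   row.names = FALSE)
  if (!is.null(out$mapping)) {
    write.csv(
      dplyr::select(out$mapping$psd_table, -dplyr::any_of("nn_distances_um")),
      file.path(outdir, "psd_table.csv"), row.names = FALSE)
    write_mask_tiff(out$mapping$segmentations$psd95$mask,
                    file.path(outdir, "psd95_mask.tif"))
  }
  if (!is.null(out$nanostruct)) {
    write.csv(out$nanostruct$nc_table,
                     file.path(outdir, "nc_table.csv"), row.names = FALSE)
  }
  record <- list(
    seed = out$seed,
    pipeline_config = unclass(cfg),
    scene_params = lapply(unclass(sp)[!vapply(sp, is.null, logical(1))],
                          function(x) if (inherits(x, "lamina_roi")) NULL else x),
    fractions = list(
      tripartite_of_synapses = out$mapping$tripartite_fraction_of_synapses,
      two_plus_nc = out$nanostruct$two_plus_fraction),
    r_version = as.character(getRversion()))
  jsonlite::write_json(record, file.path(outdir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(outdir)
}
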