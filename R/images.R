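#' Image containers
#'
#' Light S3 wrappers around plain numeric/logical/integer matrices that carry
#' the physical pixel size and acquisition metadata alongside the pixel data.
#' Rows run down the image (y) and columns across it (x); the centre of pixel
#' `[r, c]` sits at physical coordinates
#' `x = (c - 0.5) * pixel_size_um`, `y = (r - 0.5) * pixel_size_um`.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_size_nm physical pixel pitch in nanometres (102.4 for the
#'   high-resolution mapping camera, 19.97 for g-STED acquisitions).
#' @param modality one of `"highres"`, `"confocal"`, `"sted"`.
#' @param label free-text channel label (e.g. `"psd95"`, `"eaat2"`).
#' @return A `channel_image` object.
#' @export
channel_image <- function(pixels, pixel_size_nm,
                          modality = c("highres", "confocal", "sted"),
                          label = "") {
  modality <- match.arg(modality)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive number", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel intensities must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         modality = modality, label = label),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image '%s'> %d x %d px @ %.5g nm/px (%s)\n",
              x$label, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_nm, x$modality))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Binary foreground mask
#'
#' @param pixels logical matrix.
#' @param pixel_size_nm pixel pitch in nm.
#' @param provenance named list recording how the mask was made
#'   (source label, threshold method and value).
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(pixels, pixel_size_nm, provenance = list()) {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         provenance = provenance),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px @ %.5g nm/px, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              sum(x$pixels)))
  invisible(x)
}

#' Labelled object image
#'
#' Integer matrix in which background is 0 and each connected object carries a
#' dense label `1..n`.
#'
#' @param pixels integer matrix of labels.
#' @param pixel_size_nm pixel pitch in nm.
#' @return A `label_image` object.
#' @export
label_image <- function(pixels, pixel_size_nm) {
  stopifnot(is.matrix(pixels))
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         n = max(0L, max(pixels))),
    class = "label_image"
  )
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d x %d px @ %.5g nm/px, %d objects\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$n))
  invisible(x)
}

physical_extent_um <- function(img) {
  s <- img$pixel_size_nm / 1000
  c(x = ncol(img$pixels) * s, y = nrow(img$pixels) * s)
}

#' Read / write single-plane grayscale TIFF channels
#'
#' Images are written as 16-bit (default) grayscale TIFF with the pixel size
#' and channel metadata echoed into a JSON sidecar (`<file>.json`), because
#' baseline TIFF has no standard physical-calibration tag.
#'
#' @param img a [channel_image()].
#' @param path output TIFF path.
#' @param bit_depth 8 or 16.
#' @return `write_channel_tiff()` returns `path` invisibly;
#'   `read_channel_tiff()` returns a [channel_image()].
#' @export
write_channel_tiff <- function(img, path, bit_depth = 16L) {
  stopifnot(inherits(img, "channel_image"), bit_depth %in% c(8L, 16L))
  maxval <- 2^bit_depth - 1
  px <- pmin(pmax(img$pixels, 0), maxval) / maxval
  tiff::writeTIFF(px, path, bits.per.sample = bit_depth)
  meta <- list(pixel_size_nm = img$pixel_size_nm, modality = img$modality,
               label = img$label, bit_depth = bit_depth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_channel_tiff
#' @param pixel_size_nm,modality,label metadata overrides used when no JSON
#'   sidecar is present next to the TIFF.
#' @export
read_channel_tiff <- function(path, pixel_size_nm = NULL, modality = "highres",
                              label = "") {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px <- matrix(as.numeric(px), nrow = nrow(px))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size_nm)) pixel_size_nm <- meta$pixel_size_nm
    modality <- meta$modality %||% modality
    label <- meta$label %||% label
  }
  if (is.null(pixel_size_nm)) {
    stop("no pixel size given and no JSON sidecar found", call. = FALSE)
  }
  channel_image(px, pixel_size_nm, modality, label)
}

#' Write a binary mask as an 8-bit 0/255 TIFF
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  tiff::writeTIFF(ifelse(mask$pixels, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
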