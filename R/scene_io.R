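#' Write / read a scene as TIFF plus JSON side-files
#'
#' Channels are written as one multi-page 32-bit float TIFF (intensities
#' divided by a global scale so they fit the file format's \[0, 1\]
#' range); channel names, the scale, pixel size and scalar ground truth go
#' to `<prefix>.json`. Ground-truth masks, if present, are written as a
#' second multi-page TIFF `<prefix>_gt.tif`. [read_scene()] reverses the
#' round trip.
#'
#' @param sc A [scene()].
#' @param prefix Output path prefix (directories are created).
#' @return `write_scene()` returns the file paths invisibly;
#'   `read_scene()` returns the reconstructed [scene()].
#' @export
write_scene <- function(sc, prefix) {
  stopifnot(inherits(sc, "scene"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  scale <- max(1e-12, max(vapply(sc$channels, max, numeric(1))))
  tiff::writeTIFF(lapply(sc$channels, function(ch) ch / scale),
                  paste0(prefix, ".tif"), bits.per.sample = 32L)
  gt <- sc$ground_truth
  mask_names <- character()
  if (!is.null(gt)) {
    is_mask <- vapply(gt, function(g) is.matrix(g) && is.logical(g),
                      logical(1))
    mask_names <- names(gt)[is_mask]
    if (length(mask_names)) {
      tiff::writeTIFF(lapply(gt[mask_names], function(m) m * 1),
                      paste0(prefix, "_gt.tif"), bits.per.sample = 8L)
    }
  }
  scalar_gt <- if (is.null(gt)) NULL else
    gt[!vapply(gt, is.matrix, logical(1))]
  jsonlite::write_json(
    list(channels = names(sc$channels), scale = scale,
         pixel_size = sc$pixel_size, mask_names = mask_names,
         ground_truth = scalar_gt),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, c(".tif", ".json")))
}

#' @rdname write_scene
#' @export
read_scene <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  channels <- lapply(pages, function(p) p * meta$scale)
  names(channels) <- meta$channels
  gt <- as.list(meta$ground_truth)
  if (length(meta$mask_names)) {
    mpages <- tiff::readTIFF(paste0(prefix, "_gt.tif"), all = TRUE)
    masks <- lapply(mpages, function(m) m > 0.5)
    names(masks) <- meta$mask_names
    gt <- c(gt, masks)
  }
  scene(channels, pixel_size = meta$pixel_size,
        ground_truth = if (length(gt)) gt else NULL)
}
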