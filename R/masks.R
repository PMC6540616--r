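#' Binary masks (thresholded ROIs)
#'
#' Masks are plain logical matrices with the same shape as their source
#' image; every ROI used by the image quantifiers is built from them with
#' [threshold_mask()], [dilate_mask()], [invert_mask()] and
#' [combine_masks()].
#'
#' @param image Numeric matrix of intensities.
#' @param threshold Lower brightness threshold (inclusive): a pixel is in
#'   the mask iff `intensity >= threshold`.
#' @return Logical matrix.
#' @examples
#' m <- threshold_mask(matrix(0:8, 3), 4)
#' sum(m)
#' @export
threshold_mask <- function(image, threshold) {
  stopifnot(is.matrix(image), is.numeric(threshold), threshold >= 0)
  image >= threshold
}

#' Otsu automatic threshold
#'
#' Between-class-variance threshold, delegated to EBImage. This is an
#' extension for synthetic tests; the assays themselves use explicit
#' per-image thresholds.
#'
#' @param image Numeric matrix.
#' @param levels Histogram levels (default 256).
#' @return Threshold on the image's own intensity scale.
#' @export
otsu_threshold <- function(image, levels = 256) {
  r <- range(image)
  if (diff(r) == 0) return(r[1])
  thr <- EBImage::otsu(EBImage::Image((image - r[1]) / diff(r)),
                       range = c(0, 1), levels = levels)
  thr * diff(r) + r[1]
}

# shift a matrix by (dx, dy): out[i, j] = m[i + dx, j + dy], `fill` outside.
shift_matrix <- function(m, dx, dy, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr) + dx
  ci <- seq_len(nc) + dy
  ok_r <- ri >= 1 & ri <= nr
  ok_c <- ci >= 1 & ci <= nc
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- m[ri[ok_r], ci[ok_c], drop = FALSE]
  }
  out
}

# integer offsets (dx, dy) with dx^2 + dy^2 <= r^2
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

#' Dilate a mask by a Euclidean disk
#'
#' A pixel of the output is true iff its Euclidean distance to the nearest
#' true input pixel is at most `radius_px` (the "Enlarge by five pixels"
#' operation applied to MAP2 ROIs uses radius 5). Radius 0 is the identity.
#'
#' @param mask Logical matrix.
#' @param radius_px Dilation radius in pixels (>= 0); default 5.
#' @return Logical matrix; always a superset of the input.
#' @export
dilate_mask <- function(mask, radius_px = 5) {
  stopifnot(is.matrix(mask), is.logical(mask), radius_px >= 0)
  if (radius_px == 0 || !any(mask)) return(mask)
  off <- disk_offsets(radius_px)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) {
    out <- out | shift_matrix(mask, off$dx[k], off$dy[k], FALSE)
  }
  out
}

#' Erode a mask by a Euclidean disk
#'
#' Complement of the dilation of the complement; used to trim boundary
#' pixels (e.g. membrane edges) off a cell mask.
#'
#' @inheritParams dilate_mask
#' @return Logical matrix; always a subset of the input.
#' @export
erode_mask <- function(mask, radius_px = 1) {
  !dilate_mask(!mask, radius_px)
}

#' Invert a mask ("Make Inverse")
#'
#' @param mask Logical matrix.
#' @return Pixelwise complement.
#' @export
invert_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  !mask
}

#' Combine two masks with Boolean set algebra
#'
#' @param a,b Logical matrices of identical shape.
#' @param op `"and"` (intersection), `"or"` (union) or `"minus"`
#'   (set difference `a & !b`).
#' @return Logical matrix.
#' @export
combine_masks <- function(a, b, op = c("and", "or", "minus")) {
  op <- match.arg(op)
  stopifnot(is.matrix(a), is.matrix(b), is.logical(a), is.logical(b))
  if (!identical(dim(a), dim(b))) {
    abort("Mask shapes differ.", class = "synquant_shape_mismatch")
  }
  switch(op, and = a & b, or = a | b, minus = a & !b)
}

#' Connected components of a mask
#'
#' 4-connected component labeling (delegated to EBImage), with components
#' below `min_area` pixels removed to suppress noise specks.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component size in pixels (default 1).
#' @return Integer label matrix (0 = background); the number of surviving
#'   components is attached as attribute `"n"`.
#' @export
label_components <- function(mask, min_area = 1) {
  stopifnot(is.matrix(mask), is.logical(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (min_area > 1 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  ids <- sort(unique(lab[lab > 0]))
  relab <- integer(if (length(ids)) max(ids) else 0)
  relab[ids] <- seq_along(ids)
  lab[lab > 0] <- relab[lab[lab > 0]]
  attr(lab, "n") <- length(ids)
  lab
}
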