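#' Rolling-ball background subtraction
#'
#' Estimates the background of a 2D intensity image as the grayscale
#' morphological opening with a true ball (spherical-cap) structuring
#' element of the given radius — the surface traced by the top of a ball of
#' that radius rolled under the intensity landscape — and subtracts it,
#' flooring at zero. Features narrower than the ball are preserved;
#' smoothly varying background (including a constant offset) is removed
#' entirely. The co-clustering pipeline applies this with radius 14 to the
#' liprin channel before thresholding.
#'
#' The erosion/dilation pair uses the non-flat structuring element
#' `b(dx, dy) = sqrt(r^2 - dx^2 - dy^2)` over the disk `dx^2 + dy^2 <= r^2`
#' with the adjoint boundary convention (out-of-image pixels ignored), so
#' the background never exceeds the image and the output is nonnegative.
#'
#' @param image Numeric matrix.
#' @param radius_px Ball radius in pixels (>= 1); default 14. Must not
#'   exceed the smaller image dimension.
#' @return Matrix of the same shape: `image - background`, floored at 0.
#'   The background estimate is attached as attribute `"background"`.
#' @examples
#' img <- matrix(5, 32, 32); img[16, 16] <- 100
#' out <- rolling_ball_subtract(img, 14)
#' out[16, 16]  # peak preserved, flat offset removed
#' @export
rolling_ball_subtract <- function(image, radius_px = 14) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (radius_px < 1) {
    abort("`radius_px` must be >= 1.", class = "synquant_bad_radius")
  }
  if (radius_px > min(dim(image))) {
    abort("Ball radius exceeds the image size.",
          class = "synquant_bad_radius")
  }
  off <- disk_offsets(radius_px)
  h <- sqrt(radius_px^2 - off$dx^2 - off$dy^2)
  # erosion: e(x) = min_s f(x + s) - b(s)
  er <- matrix(Inf, nrow(image), ncol(image))
  for (k in seq_len(nrow(off))) {
    er <- pmin(er, shift_matrix(image, off$dx[k], off$dy[k], Inf) - h[k])
  }
  # dilation: d(x) = max_s e(x - s) + b(s)
  bg <- matrix(-Inf, nrow(image), ncol(image))
  for (k in seq_len(nrow(off))) {
    bg <- pmax(bg, shift_matrix(er, -off$dx[k], -off$dy[k], -Inf) + h[k])
  }
  out <- pmax(image - bg, 0)
  attr(out, "background") <- bg
  out
}
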