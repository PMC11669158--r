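# Directional (line) morphology for the hyphae channel. Dilation and erosion
# are computed as running max / min over the line footprint using shifted
# slices; out-of-image positions are ignored (max/min over the valid pixels
# only). With symmetric footprints this valid-pixel convention is a true
# adjunction, so closing is extensive and idempotent and opening is
# anti-extensive and idempotent, including at image borders.

#' Digital line structuring element
#'
#' Returns the (row, col) pixel offsets of a digital line of odd length
#' through the origin at one of the four supported orientations. 0 degrees is
#' horizontal, 90 vertical, 45 and 135 the two diagonals (one pixel step per
#' unit along the line). The footprint is symmetric about the origin and
#' contains it.
#'
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param length Odd integer >= 3, the number of pixels in the line.
#' @return Integer matrix with columns \code{dr}, \code{dc}, one row per
#'   footprint pixel.
#' @export
line_footprint <- function(angle, length) {
  if (!angle %in% c(0, 45, 90, 135))
    stop("line angle must be one of 0, 45, 90, 135 degrees", call. = FALSE)
  if (length < 3 || length %% 2 != 1)
    stop("line length must be an odd integer >= 3", call. = FALSE)
  k <- seq.int(-(length - 1L) / 2L, (length - 1L) / 2L)
  step <- switch(as.character(angle),
    "0"   = cbind(dr = 0L * k, dc = k),
    "45"  = cbind(dr = -k,     dc = k),
    "90"  = cbind(dr = k,      dc = 0L * k),
    "135" = cbind(dr = k,      dc = k))
  storage.mode(step) <- "integer"
  step
}

# shift a matrix so out[i, j] = img[i + dr, j + dc], filling exposed cells
shift_matrix <- function(img, dr, dc, fill) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  sr <- max(1L, 1L + dr):min(h, h + dr)
  sc <- max(1L, 1L + dc):min(w, w + dc)
  if (length(sr) > 0L && length(sc) > 0L)
    out[sr - dr, sc - dc] <- img[sr, sc, drop = FALSE]
  out
}

# grayscale dilation / erosion over an explicit offset footprint
gray_dilate_offsets <- function(img, offsets) {
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (i in seq_len(nrow(offsets)))
    out <- pmax(out, shift_matrix(img, offsets[i, 1L], offsets[i, 2L], -Inf))
  out
}

gray_erode_offsets <- function(img, offsets) {
  out <- matrix(Inf, nrow(img), ncol(img))
  for (i in seq_len(nrow(offsets)))
    out <- pmin(out, shift_matrix(img, offsets[i, 1L], offsets[i, 2L], Inf))
  out
}

check_line_args <- function(img, angles, length) {
  if (length >= min(nrow(img), ncol(img)))
    stop("line length must be smaller than both image dimensions",
         call. = FALSE)
  if (length(angles) < 1L) stop("need at least one orientation", call. = FALSE)
  invisible(NULL)
}

#' Directional grayscale closing
#'
#' Closes the Sobel contour image with digital lines at the given
#' orientations so that the hyphal outline becomes connected: for each angle
#' the grayscale closing (dilation then erosion with the same line) is
#' computed independently, and the per-angle results are combined by
#' pixel-wise maximum, which bridges gaps along any single orientation. The
#' result dominates the input pointwise (closing is extensive).
#'
#' @param img 8-bit image matrix.
#' @param angles Orientations in degrees, default \code{c(0, 45, 90, 135)}.
#' @param length Odd line length in pixels.
#' @return Closed image matrix.
#' @export
directional_close <- function(img, angles = c(0, 45, 90, 135), length = 15) {
  validate_image8(img, "image")
  check_line_args(img, angles, length)
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (a in angles) {
    fp <- line_footprint(a, length)
    out <- pmax(out, gray_erode_offsets(gray_dilate_offsets(img, fp), fp))
  }
  out
}

#' Directional binary opening
#'
#' Opens the thresholded contour mask with the same line elements used for
#' closing: per-angle binary opening (erosion then dilation), combined by
#' union, which keeps any structure elongated along at least one of the four
#' orientations and removes compact noise. The result is contained in the
#' input (opening is anti-extensive).
#'
#' @param mask Logical matrix.
#' @param angles Orientations in degrees, default \code{c(0, 45, 90, 135)}.
#' @param length Odd line length in pixels.
#' @return Logical matrix, subset of \code{mask}.
#' @export
directional_open <- function(mask, angles = c(0, 45, 90, 135), length = 15) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  check_line_args(mask, angles, length)
  img <- mask * 1
  out <- matrix(0, nrow(mask), ncol(mask))
  for (a in angles) {
    fp <- line_footprint(a, length)
    out <- pmax(out, gray_dilate_offsets(gray_erode_offsets(img, fp), fp))
  }
  out > 0.5
}

# flat disk footprint of the given pixel radius (odd-sized kernel matrix,
# origin at the center); shared by the rolling-ball opening and the
# synthetic-scene geometry
disk_kernel <- function(radius) {
  r <- as.integer(floor(radius))
  d <- seq.int(-r, r)
  k <- outer(d, d, function(a, b) as.numeric(a^2 + b^2 <= radius^2))
  k
}

#' Fill enclosed holes of a binary mask
#'
#' Wrapper around \code{EBImage::fillHull} returning a logical matrix: every
#' background region not connected to the image border is set to foreground.
#' Used so that a closed hyphal contour measures filament area rather than
#' outline length.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  filled <- EBImage::fillHull(mask * 1)
  as.matrix(filled) > 0.5
}
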