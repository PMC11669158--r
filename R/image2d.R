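# Canonical working depth is 8-bit: every image entering the pipeline is a
# numeric matrix with values in [0, 255]. The fixed bacteria threshold
# (intensity 20) only has meaning on a fixed scale, so 16-bit inputs are
# rescaled over the full nominal range at ingestion (see load_field_of_view).

#' Validate an 8-bit grayscale image matrix
#'
#' Checks the canonical image contract used throughout the package: a numeric
#' matrix, at least 3x3 (the minimum for the 3x3 kernels), all values inside
#' \code{[0, 255]} and no missing values.
#'
#' @param img A numeric matrix.
#' @param what Name used in error messages.
#' @return The validated matrix, invisibly.
#' @export
validate_image8 <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop(what, " must be at least 3x3 pixels", call. = FALSE)
  if (anyNA(img))
    stop(what, " contains missing values", call. = FALSE)
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255)
    stop(what, " has intensities outside [0, 255]", call. = FALSE)
  invisible(img)
}

#' Clamp intensities to the 8-bit range
#'
#' @param x Numeric vector or matrix.
#' @return \code{x} with values clamped to \code{[0, 255]}.
#' @export
clamp8 <- function(x) pmin(pmax(x, 0), 255)

# round-half-up on non-negative values; used wherever the bit-depth contract
# pins the rounding rule (16->8-bit conversion)
round_half_up <- function(x) floor(x + 0.5)

#' Rotate a matrix by 90 degrees counter-clockwise
#'
#' Utility used by the rotation-equivariance checks of the segmentation
#' pipeline; exact (no interpolation).
#'
#' @param m A matrix.
#' @return The rotated matrix.
#' @export
rot90 <- function(m) {
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}

#' Create a binary mask object
#'
#' A mask is a logical matrix pixel-aligned to its source image; its area is
#' the raw count of true pixels (no physical calibration).
#'
#' @param pixels Logical matrix.
#' @return An object of class \code{binary_mask}: the logical matrix with an
#'   \code{area_px} attribute.
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("mask pixels must be a logical matrix", call. = FALSE)
  structure(pixels, area_px = sum(pixels), class = c("binary_mask", "matrix"))
}

#' Mask area in pixels
#' @param mask Logical matrix (optionally of class \code{binary_mask}).
#' @return Integer count of true pixels.
#' @export
mask_area <- function(mask) sum(mask)
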