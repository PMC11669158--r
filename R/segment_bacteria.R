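# Fluorescence (bacteria) channel: per-plane rolling-ball background
# subtraction and percentile contrast enhancement, then a maximum-intensity
# projection across the focal planes and a fixed inclusive threshold.

# mean over s x s blocks (s divides the padded extent; partial edge blocks
# average their own pixels)
block_mean <- function(img, s) {
  h <- nrow(img); w <- ncol(img)
  ri <- (seq_len(h) - 1L) %/% s + 1L
  ci <- (seq_len(w) - 1L) %/% s + 1L
  sums <- rowsum(t(rowsum(img, ri)), ci)
  cnt <- tcrossprod(tabulate(ci), tabulate(ri))
  t(sums / cnt)
}

# bilinear upscale of a block-mean image back to h x w; block centers sit at
# (b - 0.5) * s + 0.5 in pixel coordinates, and the mapping is symmetric so
# the operation commutes with 90-degree rotation of square images
block_upscale <- function(bins, s, h, w) {
  up1 <- function(n, nb) {
    u <- pmin(pmax((seq_len(n) - 0.5) / s + 0.5, 1), nb)
    lo <- pmin(floor(u), nb - 1L)
    if (nb == 1L) return(list(lo = rep(1L, n), hi = rep(1L, n),
                              wt = rep(0, n)))
    list(lo = lo, hi = lo + 1L, wt = u - lo)
  }
  r <- up1(h, nrow(bins)); cc <- up1(w, ncol(bins))
  a <- bins[r$lo, cc$lo, drop = FALSE]; b <- bins[r$lo, cc$hi, drop = FALSE]
  d <- bins[r$hi, cc$lo, drop = FALSE]; e <- bins[r$hi, cc$hi, drop = FALSE]
  wr <- matrix(r$wt, h, w); wc <- matrix(cc$wt, h, w, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc +
    d * wr * (1 - wc) + e * wr * wc
}

# shrink factor used for the background estimate, following the convention
# of the classic rolling-ball implementation (larger balls roll on a more
# strongly downsampled image)
rolling_ball_shrink <- function(radius) {
  if (radius <= 10) 1L else if (radius <= 30) 2L else if (radius <= 100) 4L
  else 8L
}

# spherical (rolling-ball) structuring function: height of the ball surface
# below its lowest point, as a list of offsets and (non-positive) weights
ball_se <- function(radius) {
  r <- as.integer(floor(radius))
  d <- seq.int(-r, r)
  dist2 <- outer(d, d, function(a, b) a^2 + b^2)
  keep <- which(dist2 <= radius^2, arr.ind = TRUE)
  list(dr = d[keep[, 1L]], dc = d[keep[, 2L]],
       w = sqrt(radius^2 - dist2[keep]) - radius)
}

# grayscale erosion / dilation with a structuring function, then opening:
# the classic ball "rolled" under the surface from below
ball_opening <- function(img, radius) {
  se <- ball_se(radius)
  er <- matrix(Inf, nrow(img), ncol(img))
  for (i in seq_along(se$w))
    er <- pmin(er, shift_matrix(img, se$dr[i], se$dc[i], Inf) - se$w[i])
  di <- matrix(-Inf, nrow(img), ncol(img))
  for (i in seq_along(se$w))
    di <- pmax(di, shift_matrix(er, se$dr[i], se$dc[i], -Inf) + se$w[i])
  di
}

#' Rolling-ball background subtraction
#'
#' Removes the slowly varying fluorescence background by "rolling" a ball of
#' the given radius (pipeline default 50 px) under the image surface: the
#' background is the grayscale opening of the image with a spherical
#' structuring function, and is subtracted with the result clamped at zero.
#' As in the classic implementations, the ball rolls on a lightly
#' presmoothed (3x3 mean) and, for larger radii, block-averaged (shrunk)
#' copy of the image whose opened surface is interpolated back to full
#' resolution — rolling directly on the raw noisy image would track the
#' noise minima instead of the background level and leave the full
#' background offset in the subtracted image. The subtraction is always
#' \code{img - background}, so adding a constant offset to the input leaves
#' the output unchanged, and a flat image subtracts to all zeros.
#' Set \code{presmooth = FALSE} for the bare flat-disk
#' \code{img - opening(img)} variant (no smoothing, shrinking or ball
#' curvature), which is the reference form used by the brute-force oracle
#' tests.
#'
#' @param img 8-bit image matrix.
#' @param radius Ball radius in pixels; must be below half the smaller image
#'   dimension.
#' @param presmooth Estimate the background from the smoothed, shrunk image
#'   with the spherical ball (default \code{TRUE}).
#' @return Background-subtracted image matrix (still in \code{[0, 255]}).
#' @export
rolling_ball_subtract <- function(img, radius = 50, presmooth = TRUE) {
  validate_image8(img, "image")
  if (radius <= 0) stop("rolling-ball radius must be > 0", call. = FALSE)
  if (radius >= min(dim(img)) / 2)
    stop("rolling-ball radius must be below half the image size",
         call. = FALSE)
  if (presmooth) {
    k <- rep(1, 3) / 3
    base <- conv1d(conv1d(img, k, 1L), k, 2L)
    s <- rolling_ball_shrink(radius)
    if (s > 1L) {
      bins <- block_mean(base, s)
      bg <- block_upscale(ball_opening(bins, radius / s), s,
                          nrow(img), ncol(img))
    } else {
      bg <- ball_opening(base, radius)
    }
  } else {
    # EBImage grayscale morphology expects intensities in [0, 1]
    bg <- 255 * as.matrix(EBImage::opening(img / 255, disk_kernel(radius)))
  }
  out <- img - bg
  out[out < 0] <- 0
  out
}

#' Percentile contrast enhancement
#'
#' Linearly rescales intensities so that a fixed fraction of pixels
#' saturates: the saturation budget is split evenly between the two tails,
#' and the low/high cut intensities are the nearest-rank percentiles of the
#' pixel multiset; values are mapped so the cuts land on 0 and 255, then
#' clamped and rounded. The map is monotone non-decreasing. A constant image
#' (no contrast to stretch) maps to all zeros.
#'
#' @param img 8-bit image matrix.
#' @param saturated_percent Total percent of pixels allowed to saturate
#'   (pipeline default 0.05).
#' @return Contrast-enhanced image matrix.
#' @export
enhance_contrast <- function(img, saturated_percent = 0.05) {
  validate_image8(img, "image")
  if (saturated_percent < 0 || saturated_percent >= 100)
    stop("saturated_percent must lie in [0, 100)", call. = FALSE)
  cuts <- contrast_cuts(as.vector(img), saturated_percent)
  apply_contrast(img, cuts)
}

# nearest-rank percentile cuts of a pixel multiset, saturation split evenly
# between the tails
contrast_cuts <- function(v, saturated_percent) {
  v <- sort(v)
  n <- length(v)
  tail_frac <- saturated_percent / 2 / 100
  list(lo = v[max(1L, ceiling(n * tail_frac))],
       hi = v[min(n, max(1L, ceiling(n * (1 - tail_frac))))])
}

apply_contrast <- function(img, cuts) {
  if (cuts$hi <= cuts$lo) return(matrix(0, nrow(img), ncol(img)))
  clamp8(round((img - cuts$lo) * 255 / (cuts$hi - cuts$lo)))
}

#' Contrast enhancement of a focal stack with a shared mapping
#'
#' Computes the percentile cuts on the pooled pixel multiset of all planes
#' and applies the one resulting linear map to every plane. Sharing the map
#' keeps the relative brightness of the planes intact: enhancing each plane
#' against its own histogram would amplify a strongly defocused (dim) plane
#' until its noise floor crosses the fixed bacteria threshold.
#'
#' @param stack Non-empty list of 8-bit image matrices.
#' @param saturated_percent Total percent of (pooled) pixels allowed to
#'   saturate.
#' @return List of enhanced image matrices.
#' @export
enhance_contrast_stack <- function(stack, saturated_percent = 0.05) {
  if (is.matrix(stack)) stack <- list(stack)
  if (length(stack) == 0L) stop("empty focal stack", call. = FALSE)
  if (saturated_percent < 0 || saturated_percent >= 100)
    stop("saturated_percent must lie in [0, 100)", call. = FALSE)
  for (p in stack) validate_image8(p, "focal plane")
  cuts <- contrast_cuts(unlist(lapply(stack, as.vector)), saturated_percent)
  lapply(stack, apply_contrast, cuts = cuts)
}

#' Maximum-intensity projection of a focal stack
#'
#' Pixel-wise maximum across the planes, collapsing the z-stack so that
#' every bacterium in focus on any plane appears in one image.
#'
#' @param stack Non-empty list of image matrices with identical shape.
#' @return Projected image matrix.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) stack <- list(stack)
  if (length(stack) == 0L) stop("empty focal stack", call. = FALSE)
  dims <- vapply(stack, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("all focal planes must share one shape", call. = FALSE)
  Reduce(pmax, stack)
}

#' Segment bacteria from a fluorescence focal stack
#'
#' Applies rolling-ball background subtraction per focal plane and
#' percentile contrast enhancement with one mapping shared across the stack
#' (\code{\link{enhance_contrast_stack}}); projects the processed planes by
#' pixel-wise maximum; and thresholds the projection at the fixed intensity
#' (inclusive), yielding the bacteria mask.
#'
#' @param stack Non-empty list of 8-bit image matrices (focal planes).
#' @param config A \code{\link{pipeline_config}}.
#' @return Logical \code{binary_mask} of bacteria pixels.
#' @export
segment_bacteria <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.matrix(stack)) stack <- list(stack)
  subtracted <- lapply(stack, rolling_ball_subtract,
                       radius = config$rolling_ball_radius)
  enhanced <- enhance_contrast_stack(subtracted, config$saturated_percent)
  threshold_fixed(max_project(enhanced), config$fixed_threshold)
}
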