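# Separable convolution with symmetric (reflective) borders. Implemented as
# shifted-slice sums so borders, rounding and rotation-equivariance are fully
# under the package's control.

# symmetric reflection of out-of-range indices; repeats the reflection for
# pads wider than the image (needed for small images under wide kernels)
sym_index <- function(n, pad) {
  idx <- seq.int(1L - pad, n + pad)
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  m <- ((idx - 1L) %% period + period) %% period
  ifelse(m < n, m + 1L, period - m)
}

# 1-D convolution of a matrix along rows (margin = 1) or columns (margin = 2)
# with an odd-length kernel w, symmetric border
conv1d <- function(img, w, margin) {
  r <- (length(w) - 1L) %/% 2L
  h <- nrow(img); wd <- ncol(img)
  if (margin == 1L) {
    p <- img[sym_index(h, r), , drop = FALSE]
    out <- matrix(0, h, wd)
    for (k in seq_along(w))
      out <- out + w[k] * p[k:(k + h - 1L), , drop = FALSE]
  } else {
    p <- img[, sym_index(wd, r), drop = FALSE]
    out <- matrix(0, h, wd)
    for (k in seq_along(w))
      out <- out + w[k] * p[, k:(k + wd - 1L), drop = FALSE]
  }
  out
}

# normalized 1-D Gaussian kernel; support 3 sigma each side
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing of the bright-field channel
#'
#' Suppresses pixel noise before edge detection. The "radius" follows the
#' convention of ImageJ-style Gaussian blur and is used directly as the
#' standard deviation sigma of the kernel; the filter is separable with
#' symmetric (reflective) borders, and the output is rounded and clamped back
#' to the 8-bit range.
#'
#' @param img 8-bit image matrix.
#' @param radius Gaussian sigma in pixels (default 3, the pipeline default).
#' @return Smoothed 8-bit image matrix.
#' @export
smooth_brightfield <- function(img, radius = 3) {
  validate_image8(img, "brightfield")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("smoothing radius must be a positive number", call. = FALSE)
  w <- gaussian_kernel(radius)
  clamp8(round(conv1d(conv1d(img, w, 1L), w, 2L)))
}

#' Sobel gradient magnitude
#'
#' Applies the standard 3x3 Sobel kernel pair with symmetric borders and
#' returns the per-pixel gradient magnitude \code{sqrt(gx^2 + gy^2)},
#' computed in double precision and then clamped to [0, 255] so the result
#' feeds directly into the 256-bin auto-threshold.
#'
#' @param img 8-bit image matrix (normally the smoothed bright-field).
#' @return Gradient-magnitude image, 8-bit.
#' @export
sobel_contour <- function(img) {
  validate_image8(img, "image")
  smooth <- c(1, 2, 1)
  diff <- c(-1, 0, 1)
  gx <- conv1d(conv1d(img, smooth, 1L), diff, 2L)
  gy <- conv1d(conv1d(img, diff, 1L), smooth, 2L)
  clamp8(round(sqrt(gx^2 + gy^2)))
}
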