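#' IsoData (iterative intermeans) auto-threshold
#'
#' The "default" auto-threshold of ImageJ-style software: on the 256-bin
#' histogram the threshold is iterated as
#' \code{t <- round((mean(values <= t) + mean(values > t)) / 2)} starting
#' from the midpoint of the occupied intensity range until it stabilises.
#' Pixels strictly greater than the final threshold are foreground (the
#' bright Sobel edges); ties at the threshold go to background.
#'
#' @param img 8-bit image matrix with at least two distinct intensities.
#' @return List with \code{threshold} (integer) and \code{mask} (logical
#'   matrix, \code{img > threshold}).
#' @export
auto_threshold_default <- function(img) {
  validate_image8(img, "image")
  v <- as.integer(round(img))
  counts <- tabulate(v + 1L, nbins = 256L)
  occupied <- which(counts > 0L) - 1L
  if (length(occupied) < 2L)
    stop("degenerate input: image has fewer than 2 distinct intensities",
         call. = FALSE)
  lo <- occupied[1L]; hi <- occupied[length(occupied)]
  levels <- 0:255
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * levels)
  n_tot <- cum_n[256L]; s_tot <- cum_s[256L]
  t <- floor((lo + hi) / 2)
  for (iter in 1:256) {
    nl <- cum_n[t + 1L]; sl <- cum_s[t + 1L]
    m_low <- sl / nl
    m_high <- (s_tot - sl) / (n_tot - nl)
    t_new <- min(as.integer(round((m_low + m_high) / 2)), hi - 1L)
    if (t_new == t) break
    t <- t_new
  }
  list(threshold = t, mask = binary_mask(img > t))
}

#' Fixed-intensity threshold
#'
#' Thresholds the projected bacteria image at a fixed intensity; the rule is
#' inclusive, so pixels at exactly the threshold intensity are foreground.
#'
#' @param img 8-bit image matrix.
#' @param t Threshold intensity in \code{[0, 255]}; pipeline default 20.
#' @return Logical \code{binary_mask} of \code{img >= t}.
#' @export
threshold_fixed <- function(img, t = 20) {
  validate_image8(img, "image")
  if (t < 0 || t > 255) stop("threshold must lie in [0, 255]", call. = FALSE)
  binary_mask(img >= t)
}
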