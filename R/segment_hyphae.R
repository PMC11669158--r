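# Bright-field (hyphae) channel: Gaussian smoothing, Sobel contour,
# directional closing of the contour, IsoData auto-threshold, directional
# opening of the binary mask, optional hole filling.

#' Segment hyphae from a bright-field image
#'
#' Runs the bright-field branch of the pipeline: Gaussian smoothing to
#' suppress noise, Sobel gradient magnitude to outline the dark filaments,
#' grayscale closing with digital lines at 0/45/90/135 degrees so the
#' contour becomes connected and closed, IsoData auto-thresholding of the
#' closed contour image, binary opening with the same lines to discard
#' compact noise, and optionally (\code{config$fill_holes}) filling of
#' enclosed contour holes. At hyphal widths the closed contour band already
#' covers the filament interior, so hole filling is off by default.
#'
#' A blank or near-blank field (fewer than two distinct intensities after
#' edge detection) raises a degenerate-input error; in batch processing such
#' images are flagged and excluded rather than scored as zero.
#'
#' @param brightfield 8-bit image matrix.
#' @param config A \code{\link{pipeline_config}}.
#' @return Logical \code{binary_mask} of hyphae pixels.
#' @export
segment_hyphae <- function(brightfield, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  smoothed <- smooth_brightfield(brightfield, config$gaussian_radius)
  edges <- sobel_contour(smoothed)
  closed <- directional_close(edges, config$line_angles, config$line_length)
  th <- auto_threshold_default(closed)
  opened <- directional_open(th$mask, config$line_angles, config$line_length)
  if (config$fill_holes) opened <- fill_holes(opened)
  binary_mask(opened)
}
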