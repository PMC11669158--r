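# Synthetic two-channel micrographs with pixel-level ground truth. The
# generator emulates what the binding assay puts on the camera: dark curved
# hyphal filaments on a bright background in bright-field, and small bright
# bacterial rods spread over several defocused fluorescence focal planes,
# a controllable number of them sitting on the filaments.

#' Parameters of the synthetic micrograph generator
#'
#' Geometry is in pixels (such assays carry no standard physical calibration);
#' defaults are chosen to resemble real micrographs of such assays: a handful of
#' ~8 px wide curved filaments crossing a 512x512 field on a bright
#' (~200) background with ~80 intensity units of filament contrast, rods of
#' 7x3 px at peak intensity 180 over a dim fluorescence background (8) with
#' additive Gaussian noise (sd 3), imaged at three focal planes of
#' increasing defocus (blur sigma 1, 2, 3).
#'
#' @param height,width Field size in pixels.
#' @param n_filaments Number of hyphal filaments.
#' @param filament_width Filament width in pixels.
#' @param filament_contrast Intensity drop of a filament below the
#'   bright-field background.
#' @param bf_background Bright-field background intensity.
#' @param n_bacteria_on Rods whose centroid lies on a filament.
#' @param n_bacteria_off Rods placed clear of all filaments.
#' @param bacterium_axes Rod major and minor axis lengths in pixels.
#' @param bacterium_peak_intensity Rod fluorescence peak before defocus.
#' @param n_planes Number of focal planes.
#' @param defocus_sigmas Per-plane blur sigma (length \code{n_planes};
#'   the in-focus plane has sigma 1).
#' @param background_level Fluorescence background offset.
#' @param noise_sigma Additive Gaussian noise sd (both channels).
#' @param max_turn Per-step turning-angle bound of the filament random walk
#'   (radians); 0 gives straight filaments.
#' @param seed Integer RNG seed for the scene.
#' @return Object of class \code{synthetic_params}.
#' @export
synthetic_params <- function(height = 512, width = 512,
                             n_filaments = 3,
                             filament_width = 8,
                             filament_contrast = 80,
                             bf_background = 200,
                             n_bacteria_on = 20,
                             n_bacteria_off = 20,
                             bacterium_axes = c(7, 3),
                             bacterium_peak_intensity = 180,
                             n_planes = 3,
                             defocus_sigmas = c(1, 2, 3),
                             background_level = 8,
                             noise_sigma = 3,
                             max_turn = 0.15,
                             seed = 1L) {
  p <- as.list(environment())
  if (p$height < 64 || p$width < 64)
    stop("synthetic field must be at least 64x64", call. = FALSE)
  if (any(c(p$n_filaments, p$n_bacteria_on, p$n_bacteria_off) < 0))
    stop("counts must be >= 0", call. = FALSE)
  if (length(p$defocus_sigmas) != p$n_planes)
    stop("defocus_sigmas must have one value per focal plane", call. = FALSE)
  if (length(p$bacterium_axes) != 2L || any(p$bacterium_axes <= 0))
    stop("bacterium_axes must be two positive lengths", call. = FALSE)
  class(p) <- "synthetic_params"
  p
}

# dilate a sparse set of centerline pixels to a filament ribbon
dilate_points <- function(h, w, rows, cols, radius) {
  mask <- matrix(FALSE, h, w)
  offs <- which(disk_kernel(radius) > 0, arr.ind = TRUE)
  r0 <- as.integer(floor(radius)) + 1L
  dr <- offs[, 1L] - r0; dc <- offs[, 2L] - r0
  for (k in seq_along(rows)) {
    rr <- rows[k] + dr; cc <- cols[k] + dc
    keep <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    mask[cbind(rr[keep], cc[keep])] <- TRUE
  }
  mask
}

#' Generate hyphal filament geometry
#'
#' Each filament centerline is a persistent random walk: it enters the field
#' from a random border point heading inward, advances in unit-pixel steps,
#' and turns by at most \code{max_turn} radians per step, producing the
#' smooth curvature of real hyphae; the walk ends when it leaves the field.
#' The truth mask is the dilation of all centerlines to the filament width.
#' Uses R's current RNG stream; seed it for reproducibility.
#'
#' @param params A \code{\link{synthetic_params}}.
#' @return List with \code{centerlines} (list of n x 2 matrices of row/col
#'   positions) and \code{truth_mask} (logical matrix).
#' @export
generate_filaments <- function(params) {
  h <- params$height; w <- params$width
  centerlines <- vector("list", params$n_filaments)
  mask <- matrix(FALSE, h, w)
  radius <- params$filament_width / 2
  if (params$n_filaments > 0) for (f in seq_len(params$n_filaments)) {
    side <- sample.int(4L, 1L)
    if (side == 1L) {        # top edge, heading down
      pos <- c(1, stats::runif(1, 1, w)); theta <- stats::runif(1, 0.25, pi - 0.25)
    } else if (side == 2L) { # bottom edge, heading up
      pos <- c(h, stats::runif(1, 1, w)); theta <- stats::runif(1, -pi + 0.25, -0.25)
    } else if (side == 3L) { # left edge, heading right
      pos <- c(stats::runif(1, 1, h), 1); theta <- stats::runif(1, -pi / 2 + 0.25, pi / 2 - 0.25)
    } else {                 # right edge, heading left
      pos <- c(stats::runif(1, 1, h), w); theta <- stats::runif(1, pi / 2 + 0.25, 3 * pi / 2 - 0.25)
    }
    # angle convention: theta measured so rows advance by sin, cols by cos
    pts <- matrix(NA_real_, h + w, 2L)
    n_pts <- 0L
    repeat {
      n_pts <- n_pts + 1L
      pts[n_pts, ] <- pos
      pos <- pos + c(sin(theta), cos(theta))
      if (params$max_turn > 0)
        theta <- theta + stats::runif(1, -params$max_turn, params$max_turn)
      if (pos[1] < 1 || pos[1] > h || pos[2] < 1 || pos[2] > w) break
      if (n_pts >= nrow(pts)) break
    }
    line <- pts[seq_len(n_pts), , drop = FALSE]
    centerlines[[f]] <- line
    rc <- unique(cbind(pmin(h, pmax(1L, round(line[, 1]))),
                       pmin(w, pmax(1L, round(line[, 2])))))
    mask <- mask | dilate_points(h, w, rc[, 1], rc[, 2], radius)
  }
  list(centerlines = centerlines, truth_mask = mask)
}

# rasterize one rod (rotated filled ellipse) into a logical mask
rasterize_rod <- function(h, w, center, axes, theta) {
  a <- axes[1] / 2; b <- axes[2] / 2
  ext <- ceiling(a) + 1L
  rr <- max(1L, floor(center[1] - ext)):min(h, ceiling(center[1] + ext))
  cc <- max(1L, floor(center[2] - ext)):min(w, ceiling(center[2] + ext))
  mask <- matrix(FALSE, h, w)
  if (length(rr) == 0L || length(cc) == 0L) return(mask)
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  mask[rr, cc] <- (u / a)^2 + (v / b)^2 <= 1
  mask
}

#' Place bacterial rods on and off the filaments
#'
#' On-filament rods are centered on uniformly sampled filament pixels with
#' uniform random orientation. Off-filament rods are centered on background
#' pixels whose distance to the nearest filament pixel exceeds the rod's
#' major axis, so a pure "non-binder" scene has exactly zero truth overlap
#' (a clean negative control). Uses R's current RNG stream.
#'
#' @param truth_hyphae_mask Logical filament mask.
#' @param params A \code{\link{synthetic_params}}.
#' @return List with \code{poses} (data frame: row, col, theta, on_filament),
#'   \code{truth_bacteria_mask}, \code{truth_overlap_mask}.
#' @export
place_bacteria <- function(truth_hyphae_mask, params) {
  h <- params$height; w <- params$width
  if (params$n_bacteria_on > 0 && !any(truth_hyphae_mask))
    stop("cannot place on-filament bacteria: no filaments", call. = FALSE)
  major <- max(params$bacterium_axes)
  on_idx <- which(truth_hyphae_mask)
  # clearance: centroid farther than the major axis from any filament pixel
  clear_zone <- as.matrix(EBImage::dilate(truth_hyphae_mask * 1,
                                          disk_kernel(major))) > 0.5
  off_idx <- which(!clear_zone)
  if (params$n_bacteria_off > 0 && length(off_idx) == 0L)
    stop("field too crowded: no off-filament positions left", call. = FALSE)
  n_on <- params$n_bacteria_on; n_off <- params$n_bacteria_off
  # one (center, orientation) draw pair per rod, on-filament rods first, so
  # a scene with more on-filament rods extends the same prefix of placements
  draw_rod <- function(pool)
    c(pool[sample.int(length(pool), 1L)], stats::runif(1, 0, pi))
  draws <- vapply(seq_len(n_on + n_off), function(k) {
    draw_rod(if (k <= n_on) on_idx else off_idx)
  }, numeric(2))
  idx <- if (n_on + n_off > 0) as.integer(draws[1L, ]) else integer(0)
  poses <- data.frame(
    row = (idx - 1L) %% h + 1L,
    col = (idx - 1L) %/% h + 1L,
    theta = if (length(idx) > 0) draws[2L, ] else numeric(0),
    on_filament = rep(c(TRUE, FALSE), c(n_on, n_off)))
  bmask <- matrix(FALSE, h, w)
  for (k in seq_len(nrow(poses)))
    bmask <- bmask | rasterize_rod(h, w, c(poses$row[k], poses$col[k]),
                                   params$bacterium_axes, poses$theta[k])
  list(poses = poses,
       truth_bacteria_mask = bmask,
       truth_overlap_mask = bmask & truth_hyphae_mask)
}

#' Render a complete synthetic scene
#'
#' Seeds R's RNG from \code{params$seed}, generates filaments and bacteria,
#' and renders both channels at 8 bits: the bright-field image is the bright
#' background minus the filament contrast applied through a softened
#' (slightly blurred) filament mask, plus noise; each fluorescence plane is
#' the rod intensity image blurred by that plane's defocus sigma, plus the
#' background offset and noise. Ground-truth masks and the truth coverage
#' percentage are bundled with the rendered field of view.
#'
#' @param params A \code{\link{synthetic_params}}.
#' @param strain,replicate,position Metadata attached to the field of view
#'   (defaults "synthetic", 1, 1).
#' @return Object of class \code{synthetic_scene}: list with \code{fov},
#'   \code{truth_hyphae_mask}, \code{truth_bacteria_mask},
#'   \code{truth_overlap_mask}, \code{truth_percent_covered}, \code{poses},
#'   \code{params}.
#' @export
render_scene <- function(params, strain = "synthetic", replicate = 1L,
                         position = 1L) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)
  h <- params$height; w <- params$width
  fil <- generate_filaments(params)
  bac <- place_bacteria(fil$truth_mask, params)

  soft <- conv1d(conv1d(fil$truth_mask * 1, gaussian_kernel(1), 1L),
                 gaussian_kernel(1), 2L)
  bf <- params$bf_background - params$filament_contrast * soft
  if (params$noise_sigma > 0)
    bf <- bf + stats::rnorm(h * w, 0, params$noise_sigma)
  bf <- clamp8(round(bf))

  signal <- bac$truth_bacteria_mask * params$bacterium_peak_intensity
  planes <- lapply(params$defocus_sigmas, function(s) {
    g <- gaussian_kernel(s)
    pl <- conv1d(conv1d(signal, g, 1L), g, 2L) + params$background_level
    if (params$noise_sigma > 0)
      pl <- pl + stats::rnorm(h * w, 0, params$noise_sigma)
    clamp8(round(pl))
  })

  truth_h <- sum(fil$truth_mask)
  truth_cov <- if (truth_h > 0) 100 * sum(bac$truth_overlap_mask) / truth_h
               else NA_real_
  fov <- field_of_view(
    id = sprintf("%s_r%d_p%d_seed%d", gsub("/", "-", strain), replicate,
                 position, params$seed),
    strain = strain, replicate = replicate, position = position,
    brightfield = bf, fluorescence = planes)
  structure(list(fov = fov,
                 truth_hyphae_mask = fil$truth_mask,
                 truth_bacteria_mask = bac$truth_bacteria_mask,
                 truth_overlap_mask = bac$truth_overlap_mask,
                 truth_percent_covered = truth_cov,
                 poses = bac$poses,
                 params = params),
            class = "synthetic_scene")
}

#' Write a synthetic benchmark to disk
#'
#' Generates a grid of conditions x biological replicates x slide positions
#' (the acquisition design of the binding assay: by default 3 positions on 3
#' days, nine images per strain), writes each scene as a single-page
#' bright-field TIFF plus a multi-page fluorescence TIFF, and writes a
#' manifest CSV (readable by \code{\link{read_manifest}}) and a ground-truth
#' CSV with the truth coverage of every image. Scene seeds are derived from
#' \code{seed} and the scene index, so the grid is reproducible piecewise.
#'
#' @param dir Output directory (created if needed).
#' @param conditions Data frame with columns \code{strain},
#'   \code{n_bacteria_on}, \code{n_bacteria_off} (one row per synthetic
#'   "strain").
#' @param replicates,positions Biological replicates and slide positions
#'   per condition (defaults 3 and 3).
#' @param base_params A \code{\link{synthetic_params}} supplying everything
#'   except counts and seed.
#' @param seed Integer master seed.
#' @return List with \code{manifest_path}, \code{truth_path} and the truth
#'   data frame, invisibly.
#' @export
generate_benchmark <- function(dir, conditions, replicates = 3,
                               positions = 3,
                               base_params = synthetic_params(),
                               seed = 1L) {
  stopifnot(is.data.frame(conditions),
            all(c("strain", "n_bacteria_on", "n_bacteria_off") %in%
                  names(conditions)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(); truth <- list(); scene_i <- 0L
  for (ci in seq_len(nrow(conditions))) {
    for (rep_i in seq_len(replicates)) {
      for (pos_i in seq_len(positions)) {
        scene_i <- scene_i + 1L
        p <- base_params
        p$n_bacteria_on <- conditions$n_bacteria_on[ci]
        p$n_bacteria_off <- conditions$n_bacteria_off[ci]
        p$seed <- (as.integer(seed) * 1009L + scene_i) %% .Machine$integer.max
        scene <- render_scene(p, strain = conditions$strain[ci],
                              replicate = rep_i, position = pos_i)
        stem <- sprintf("scene%03d", scene_i)
        bf_path <- file.path(dir, paste0(stem, "_bf.tif"))
        fl_path <- file.path(dir, paste0(stem, "_fl.tif"))
        write_gray_tiff(scene$fov$brightfield, bf_path)
        write_gray_tiff(scene$fov$fluorescence, fl_path)
        man[[scene_i]] <- data.frame(
          id = scene$fov$id,
          brightfield_path = basename(bf_path),
          fluorescence_paths = basename(fl_path),
          strain = conditions$strain[ci], replicate = rep_i,
          position = pos_i, stringsAsFactors = FALSE)
        truth[[scene_i]] <- data.frame(
          id = scene$fov$id, strain = conditions$strain[ci],
          replicate = rep_i, position = pos_i,
          truth_percent_covered = scene$truth_percent_covered,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, man)
  truth_df <- do.call(rbind, truth)
  manifest_path <- file.path(dir, "manifest.csv")
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  utils::write.csv(truth_df, truth_path, row.names = FALSE)
  invisible(list(manifest_path = manifest_path, truth_path = truth_path,
                 truth = truth_df))
}
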