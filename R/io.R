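# Image, manifest and results I/O. Images travel as grayscale TIFF
# (single- or multi-page); a multi-page TIFF is interpreted as the
# fluorescence focal stack, the bright-field channel as a one-page file,
# mirroring how the two channels are acquired separately on the microscope.

#' Read a grayscale TIFF as a list of 8-bit image matrices
#'
#' Each page becomes one numeric matrix in \code{[0, 255]}. 16-bit pages are
#' converted by linear scaling of the full nominal range
#' (\code{round(v * 255 / 65535)}, half up), so a given physical intensity
#' always maps to the same 8-bit value regardless of per-image content.
#' RGB or multi-sample images are rejected.
#'
#' @param path Path to a TIFF file.
#' @return List of numeric matrices, one per page, in file order.
#' @export
read_gray_tiff <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) != 2L)
      stop("non-grayscale image (multiple samples per pixel): ", path,
           call. = FALSE)
    bits <- attr(p, "bits.per.sample")
    m <- matrix(as.numeric(p), nrow(p), ncol(p))
    if (!is.null(bits) && bits == 16L) {
      m <- round_half_up(m * 255 / 65535)
    } else if (!is.null(bits) && !bits %in% c(8L, 16L)) {
      stop("unsupported bit depth (", bits, "): ", path, call. = FALSE)
    }
    validate_image8(m, path)
    m
  })
}

#' Write 8-bit image matrices as a (multi-page) grayscale TIFF
#'
#' @param images A matrix or list of matrices with values in \code{[0, 255]}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gray_tiff <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  scaled <- lapply(images, function(m) round(clamp8(m)) / 255)
  tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
  invisible(path)
}

#' Assemble a field of view
#'
#' One field of view is one acquired slide position: a single bright-field
#' image of the hyphae plus an ordered fluorescence focal stack of the
#' labeled bacteria, with strain / biological replicate / position metadata.
#' All images must share one pixel grid.
#'
#' @param id Identifier string.
#' @param strain Strain label (e.g. \code{"EcN/chi"}).
#' @param replicate Positive integer biological-replicate index.
#' @param position Positive integer slide-position index.
#' @param brightfield 8-bit image matrix.
#' @param fluorescence List of 8-bit image matrices (focal planes), length
#'   at least 1.
#' @return Object of class \code{field_of_view}.
#' @export
field_of_view <- function(id, strain, replicate, position,
                          brightfield, fluorescence) {
  if (is.matrix(fluorescence)) fluorescence <- list(fluorescence)
  if (length(fluorescence) < 1L)
    stop("fluorescence stack must have at least one plane", call. = FALSE)
  validate_image8(brightfield, "brightfield")
  for (p in fluorescence) validate_image8(p, "fluorescence plane")
  dims <- vapply(c(list(brightfield), fluorescence), dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all images in a field of view must share one height and width",
         call. = FALSE)
  if (replicate < 1 || position < 1)
    stop("replicate and position must be positive integers", call. = FALSE)
  structure(list(id = as.character(id), strain = as.character(strain),
                 replicate = as.integer(replicate),
                 position = as.integer(position),
                 brightfield = brightfield, fluorescence = fluorescence),
            class = "field_of_view")
}

#' Read a sample manifest
#'
#' The manifest is a CSV with columns \code{brightfield_path},
#' \code{fluorescence_paths} (one or more paths separated by \code{";"}, in
#' focal-plane order), \code{strain}, \code{replicate} and \code{position}.
#' Paths are resolved relative to the manifest's directory;
#' (strain, replicate, position) must be unique.
#'
#' @param path Path to the manifest CSV.
#' @param check_paths Verify at load time that every referenced image file
#'   exists (default \code{TRUE}).
#' @return Data frame of manifest rows with absolute paths.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("brightfield_path", "fluorescence_paths", "strain",
                "replicate", "position")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0L)
    stop("manifest lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(man) == 0L) stop("manifest is empty", call. = FALSE)
  key <- paste(man$strain, man$replicate, man$position)
  if (anyDuplicated(key))
    stop("duplicate (strain, replicate, position) in manifest", call. = FALSE)
  base <- dirname(normalizePath(path))
  absolutize <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                   file.path(base, p))
  man$brightfield_path <- absolutize(man$brightfield_path)
  man$fluorescence_paths <- vapply(strsplit(man$fluorescence_paths, ";"),
    function(ps) paste(absolutize(trimws(ps)), collapse = ";"), character(1))
  if (check_paths) {
    all_paths <- c(man$brightfield_path,
                   unlist(strsplit(man$fluorescence_paths, ";")))
    bad <- all_paths[!file.exists(all_paths)]
    if (length(bad) > 0L)
      stop("manifest references missing files: ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  man
}

#' Load one field of view from a manifest row
#'
#' Reads the bright-field TIFF (one page) and the fluorescence TIFF(s);
#' a multi-page fluorescence file contributes its pages in order as focal
#' planes. 16-bit input is converted to the canonical 8-bit range.
#'
#' @param row One-row data frame (or list) with the manifest columns.
#' @return A \code{field_of_view}.
#' @export
load_field_of_view <- function(row) {
  bf_pages <- read_gray_tiff(row$brightfield_path)
  if (length(bf_pages) != 1L)
    stop("bright-field image must be a single page: ", row$brightfield_path,
         call. = FALSE)
  fl_paths <- trimws(strsplit(row$fluorescence_paths, ";")[[1]])
  planes <- unlist(lapply(fl_paths, read_gray_tiff), recursive = FALSE)
  id <- if (!is.null(row$id)) row$id else
    paste(row$strain, row$replicate, row$position, sep = "_")
  field_of_view(id = id, strain = row$strain, replicate = row$replicate,
                position = row$position, brightfield = bf_pages[[1]],
                fluorescence = planes)
}

results_columns <- c("id", "strain", "replicate", "position",
                     "hyphae_area_px", "bacteria_area_px", "overlap_area_px",
                     "percent_hyphae_covered", "percent_bacteria_on_hyphae")

#' Write a coverage results table
#'
#' One row per field of view, fixed column order
#' (id, strain, replicate, position, the three pixel areas,
#' percent_hyphae_covered, percent_bacteria_on_hyphae); integer area columns
#' round-trip losslessly through the CSV.
#'
#' @param results Data frame of per-image coverage results (as returned by
#'   \code{\link{run_batch}}).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results table must be a non-empty data frame", call. = FALSE)
  missing <- setdiff(results_columns, names(results))
  if (length(missing) > 0L)
    stop("results lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(results[, results_columns], path, row.names = FALSE)
  invisible(path)
}
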