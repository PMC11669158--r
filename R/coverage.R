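# The headline statistic: percent of hyphal area covered by bacteria,
# computed on the two segmentation masks in the shared pixel grid (the two
# channels are co-acquired, so no registration step is applied).

#' Coverage of hyphae by bacteria
#'
#' Computes the overlap of the bacteria and hyphae masks and the two derived
#' percentages: \code{percent_hyphae_covered} (overlap / hyphae area, the
#' headline adhesion statistic) and the auxiliary
#' \code{percent_bacteria_on_hyphae} (overlap / bacteria area; 0 when no
#' bacteria were segmented). An empty hyphae mask leaves the statistic
#' undefined and raises an error; batch callers flag such images and exclude
#' them from group statistics.
#'
#' @param hyphae Logical matrix (hyphae mask).
#' @param bacteria Logical matrix (bacteria mask), same shape.
#' @return List of class \code{coverage_result} with elements
#'   \code{hyphae_area_px}, \code{bacteria_area_px}, \code{overlap_area_px},
#'   \code{percent_hyphae_covered}, \code{percent_bacteria_on_hyphae}.
#' @export
compute_coverage <- function(hyphae, bacteria) {
  if (!identical(dim(hyphae), dim(bacteria)))
    stop("hyphae and bacteria masks must share one shape", call. = FALSE)
  h_area <- sum(hyphae)
  if (h_area == 0L)
    stop("undefined statistic: hyphae mask is empty", call. = FALSE)
  b_area <- sum(bacteria)
  ov <- sum(hyphae & bacteria)
  structure(list(
    hyphae_area_px = as.integer(h_area),
    bacteria_area_px = as.integer(b_area),
    overlap_area_px = as.integer(ov),
    percent_hyphae_covered = 100 * ov / h_area,
    percent_bacteria_on_hyphae = if (b_area > 0L) 100 * ov / b_area else 0
  ), class = "coverage_result")
}

#' Process one field of view through the full pipeline
#'
#' Segments hyphae from the bright-field image and bacteria from the
#' fluorescence stack, then computes the coverage statistics. Fully
#' deterministic: identical inputs give bit-identical results.
#'
#' @param fov A \code{\link{field_of_view}}.
#' @param config A \code{\link{pipeline_config}}.
#' @return A \code{coverage_result}.
#' @export
process_field_of_view <- function(fov, config = pipeline_config()) {
  stopifnot(inherits(fov, "field_of_view"))
  hyphae <- segment_hyphae(fov$brightfield, config)
  bacteria <- segment_bacteria(fov$fluorescence, config)
  compute_coverage(hyphae, bacteria)
}

#' Run the pipeline over a manifest
#'
#' Processes every manifest row in order, one coverage result per field of
#' view. Per-image failures (unreadable files, blank fields, empty hyphae
#' masks) are caught, flagged in the \code{status} / \code{message} columns
#' and excluded from downstream group statistics; they never abort the
#' batch. A per-strain summary of processed counts is printed when
#' \code{verbose}.
#'
#' @param manifest Data frame from \code{\link{read_manifest}} (or built in
#'   code with the same columns).
#' @param config A \code{\link{pipeline_config}}.
#' @param verbose Print a per-strain summary (default \code{FALSE}).
#' @return Data frame with the result columns
#'   (id, strain, replicate, position, areas, percentages) plus
#'   \code{status} (\code{"ok"} or \code{"error"}) and \code{message}.
#' @export
run_batch <- function(manifest, config = pipeline_config(),
                      verbose = FALSE) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("manifest must be a non-empty data frame", call. = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, , drop = FALSE]
    id <- if (!is.null(row$id)) row$id else
      paste(row$strain, row$replicate, row$position, sep = "_")
    res <- tryCatch({
      cov <- process_field_of_view(load_field_of_view(row), config)
      data.frame(id = id, strain = row$strain, replicate = row$replicate,
                 position = row$position,
                 hyphae_area_px = cov$hyphae_area_px,
                 bacteria_area_px = cov$bacteria_area_px,
                 overlap_area_px = cov$overlap_area_px,
                 percent_hyphae_covered = cov$percent_hyphae_covered,
                 percent_bacteria_on_hyphae = cov$percent_bacteria_on_hyphae,
                 status = "ok", message = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = id, strain = row$strain, replicate = row$replicate,
                 position = row$position,
                 hyphae_area_px = NA_integer_, bacteria_area_px = NA_integer_,
                 overlap_area_px = NA_integer_,
                 percent_hyphae_covered = NA_real_,
                 percent_bacteria_on_hyphae = NA_real_,
                 status = "error", message = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (verbose) {
    tab <- table(out$strain, out$status)
    message("processed fields of view per strain:")
    for (s in rownames(tab))
      message("  ", s, ": ", sum(tab[s, ]), " (ok: ",
              if ("ok" %in% colnames(tab)) tab[s, "ok"] else 0L, ")")
  }
  out
}

#' Process in-memory fields of view
#'
#' Same error-isolation contract as \code{\link{run_batch}} but over a list
#' of already-loaded \code{field_of_view} objects (used with the synthetic
#' generator, where scenes never touch disk).
#'
#' @param fovs List of \code{field_of_view} objects.
#' @param config A \code{\link{pipeline_config}}.
#' @return Data frame with the same columns as \code{\link{run_batch}}.
#' @export
process_fovs <- function(fovs, config = pipeline_config()) {
  if (length(fovs) == 0L) stop("no fields of view supplied", call. = FALSE)
  man_like <- lapply(fovs, function(fov) {
    res <- tryCatch({
      cov <- process_field_of_view(fov, config)
      data.frame(id = fov$id, strain = fov$strain,
                 replicate = fov$replicate, position = fov$position,
                 hyphae_area_px = cov$hyphae_area_px,
                 bacteria_area_px = cov$bacteria_area_px,
                 overlap_area_px = cov$overlap_area_px,
                 percent_hyphae_covered = cov$percent_hyphae_covered,
                 percent_bacteria_on_hyphae = cov$percent_bacteria_on_hyphae,
                 status = "ok", message = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = fov$id, strain = fov$strain,
                 replicate = fov$replicate, position = fov$position,
                 hyphae_area_px = NA_integer_, bacteria_area_px = NA_integer_,
                 overlap_area_px = NA_integer_,
                 percent_hyphae_covered = NA_real_,
                 percent_bacteria_on_hyphae = NA_real_,
                 status = "error", message = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, man_like)
  rownames(out) <- NULL
  out
}
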