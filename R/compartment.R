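#' Segment nuclei from a DAPI channel
#'
#' The DAPI frame is min-max normalized to [0, 1] and thresholded with Otsu's
#' method; connected components smaller than \code{min_area_um2} are removed
#' as specks. A flat (constant) frame yields an empty mask with a warning
#' rather than an error.
#'
#' @param dapi An [intensity_frame()] of the DAPI channel.
#' @param min_area_um2 Area floor for retained nuclei, in um^2.
#' @return Logical matrix marking nuclear pixels.
#' @examples
#' fr <- make_fluorescence_frames(fluor_frames_spec(
#'   frame_shape = c(128, 128), n_cells = 3, seed = 1))
#' mean(segment_nuclei(fr$dapi) == fr$truth$nuclear)
#' @export
segment_nuclei <- function(dapi, min_area_um2 = 10) {
  stopifnot(inherits(dapi, "intensity_frame"))
  norm <- minmax_norm(dapi$pixels)
  if (max(norm) == 0) {
    warning("flat DAPI frame: returning an empty nuclear mask")
    return(matrix(FALSE, nrow(dapi$pixels), ncol(dapi$pixels)))
  }
  thr <- EBImage::otsu(as_eb(norm), range = c(0, 1))
  mask <- norm > thr
  drop_small_components(mask, ceiling(min_area_um2 / pixel_area(dapi)))
}

#' Segment the cytoplasmic compartment from a phalloidin channel
#'
#' The phalloidin frame is min-max normalized, morphologically closed with a
#' disc structuring element of physical diameter \code{closing_diameter_um}
#' (6 um by default, bridging thin gaps in the actin stain), and thresholded
#' with Otsu's method to give the whole-cell footprint. The cytoplasmic mask
#' is the footprint minus the nuclear mask, so the two compartments are
#' disjoint by construction.
#'
#' @param phalloidin An [intensity_frame()] of the phalloidin channel.
#' @param nuclear_mask Logical matrix from [segment_nuclei()], same shape.
#' @param closing_diameter_um Diameter of the closing disc in um.
#' @param min_area_um2 Area floor for retained footprint components.
#' @return Logical matrix marking cytoplasmic pixels (footprint minus nuclei).
#' @export
segment_cytoplasm <- function(phalloidin, nuclear_mask,
                              closing_diameter_um = 6, min_area_um2 = 10) {
  stopifnot(inherits(phalloidin, "intensity_frame"),
            all(dim(nuclear_mask) == dim(phalloidin$pixels)))
  radius_px <- round(closing_diameter_um / 2 / phalloidin$pixel_size)
  if (radius_px < 1)
    stop("closing disc is below one pixel: pixel_size too coarse for a ",
         closing_diameter_um, " um element")
  norm <- minmax_norm(phalloidin$pixels)
  if (max(norm) == 0) {
    warning("flat phalloidin frame: returning an empty cytoplasmic mask")
    return(matrix(FALSE, nrow(norm), ncol(norm)))
  }
  # pad with background before closing so the border is not treated as object
  pad <- radius_px + 1L
  padded <- matrix(0, nrow(norm) + 2L * pad, ncol(norm) + 2L * pad)
  padded[pad + seq_len(nrow(norm)), pad + seq_len(ncol(norm))] <- norm
  closed <- as.matrix(EBImage::closing(as_eb(padded), disc_brush(radius_px)))
  closed <- closed[pad + seq_len(nrow(norm)), pad + seq_len(ncol(norm))]
  thr <- EBImage::otsu(as_eb(pmin(pmax(closed, 0), 1)), range = c(0, 1))
  footprint <- closed > thr
  footprint <- drop_small_components(footprint,
                                     ceiling(min_area_um2 / pixel_area(phalloidin)))
  footprint & !nuclear_mask
}

#' Mean marker intensity per compartment for one frame
#'
#' Applies the compartment masks to the marker channel and reports the mean
#' staining intensity and physical area of each compartment. An empty
#' compartment yields an NA mean (flagged, not an error).
#'
#' @param marker An [intensity_frame()] of the marker (e.g. GLI1 or p53)
#'   channel.
#' @param masks List with logical elements \code{nuclear} and
#'   \code{cytoplasmic}, same shape as the marker, disjoint.
#' @param frame_id Identifier recorded in the result.
#' @return One-row data.frame: frame_id, nuclear_mean, cytoplasmic_mean,
#'   nuclear_area_um2, cytoplasmic_area_um2.
#' @export
quantify_frame <- function(marker, masks, frame_id = "frame") {
  stopifnot(inherits(marker, "intensity_frame"),
            is.list(masks), all(dim(masks$nuclear) == dim(marker$pixels)),
            all(dim(masks$cytoplasmic) == dim(marker$pixels)))
  if (any(masks$nuclear & masks$cytoplasmic))
    stop("nuclear and cytoplasmic masks overlap; compartments must be disjoint")
  comp_mean <- function(m) if (any(m)) mean(marker$pixels[m]) else NA_real_
  data.frame(frame_id = frame_id,
             nuclear_mean = comp_mean(masks$nuclear),
             cytoplasmic_mean = comp_mean(masks$cytoplasmic),
             nuclear_area_um2 = sum(masks$nuclear) * pixel_area(marker),
             cytoplasmic_area_um2 = sum(masks$cytoplasmic) * pixel_area(marker))
}

#' Segment and quantify one three-channel frame
#'
#' Convenience composition of [segment_nuclei()], [segment_cytoplasm()] and
#' [quantify_frame()].
#'
#' @param dapi,phalloidin,marker The three [intensity_frame()] channels.
#' @param frame_id Identifier for the result row.
#' @param ... Passed to the segmentation steps.
#' @return As [quantify_frame()], with the masks attached as attribute
#'   \code{masks}.
#' @export
quantify_if_frame <- function(dapi, phalloidin, marker, frame_id = "frame", ...) {
  nuc <- segment_nuclei(dapi, ...)
  cyt <- segment_cytoplasm(phalloidin, nuc)
  res <- quantify_frame(marker, list(nuclear = nuc, cytoplasmic = cyt), frame_id)
  attr(res, "masks") <- list(nuclear = nuc, cytoplasmic = cyt)
  res
}

#' Average per-frame compartment intensities within an image set
#'
#' Frames flagged by the reviewer (out-of-focus) are excluded, then per-frame
#' means are averaged with equal frame weights and the across-frame standard
#' deviation reported, mirroring masked-observer QC followed by per-set
#' averaging.
#'
#' @param results data.frame of rows from [quantify_frame()].
#' @param excluded_frames Character vector of frame_ids to drop.
#' @param condition Label for the set.
#' @return One-row data.frame: condition, n_frames, n_excluded, nuclear_mean,
#'   nuclear_sd, cytoplasmic_mean, cytoplasmic_sd.
#' @export
summarize_set <- function(results, excluded_frames = character(),
                          condition = "condition") {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  unknown <- setdiff(excluded_frames, results$frame_id)
  if (length(unknown))
    warning("excluded frame ids not present in results: ",
            paste(unknown, collapse = ", "))
  keep <- !(results$frame_id %in% excluded_frames)
  if (!any(keep))
    stop("all frames excluded: nothing to summarize for '", condition, "'")
  r <- results[keep, , drop = FALSE]
  data.frame(condition = condition, n_frames = nrow(r),
             n_excluded = sum(!keep),
             nuclear_mean = mean(r$nuclear_mean, na.rm = TRUE),
             nuclear_sd = stats::sd(r$nuclear_mean, na.rm = TRUE),
             cytoplasmic_mean = mean(r$cytoplasmic_mean, na.rm = TRUE),
             cytoplasmic_sd = stats::sd(r$cytoplasmic_mean, na.rm = TRUE))
}
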