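# SAbGal positive-area scoring: Sobel-based cell segmentation of brightfield
# color images, then HSV hue-window thresholding of the blue-green reaction
# product inside cells.

# luminance (Rec. 709) grayscale of a color_frame
luminance <- function(frame) {
  px <- frame$pixels
  0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
}

#' Segment cell area from a brightfield color image (Sobel method)
#'
#' Converts to luminance, takes the Sobel gradient magnitude, thresholds it
#' (Otsu), then dilates, fills holes and erodes to turn the edge response
#' into solid cell regions; objects below an area floor are discarded. A
#' uniform image yields an empty mask with a warning.
#'
#' @param frame A [color_frame()].
#' @param dilate_px,erode_px Radii (pixels) of the edge-closing dilation and
#'   the compensating erosion. The erosion default exceeds the dilation by
#'   one pixel to absorb the half-width of the Sobel edge response, which
#'   otherwise leaves the mask one pixel wide of the true boundary.
#' @param min_object_um2 Minimum retained object area in um^2.
#' @return Logical cell mask.
#' @export
segment_cells_brightfield <- function(frame, dilate_px = 2, erode_px = 3,
                                      min_object_um2 = 50) {
  stopifnot(inherits(frame, "color_frame"))
  gray <- luminance(frame)
  grad <- sobel_magnitude(gray)
  if (max(grad) - min(grad) < 1e-9) {
    warning("uniform brightfield image: returning an empty cell mask")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  edges <- grad > otsu_threshold(grad)
  m <- EBImage::dilate(as_eb(edges * 1), disc_brush(dilate_px))
  m <- EBImage::fillHull(m)
  m <- EBImage::erode(m, disc_brush(erode_px))
  mask <- as.matrix(m) > 0.5
  drop_small_components(mask, ceiling(min_object_um2 / pixel_area(frame)))
}

#' Positive-staining mask by HSV hue window
#'
#' A pixel is scored SAbGal-positive when it lies inside the cell mask and its
#' HSV hue falls in the closed window [\code{hue_lo}, \code{hue_hi}]
#' (default 0.265-0.58, the blue-green reaction product). Because hue is
#' undefined on achromatic pixels, a minimum-saturation gate \code{s_min}
#' (default 0.1) additionally excludes near-gray pixels; set it to 0 to
#' threshold on hue alone.
#'
#' @param frame A [color_frame()].
#' @param cell_mask Logical matrix, same shape.
#' @param hue_lo,hue_hi Closed hue-window bounds in [0, 1].
#' @param s_min Minimum saturation for a pixel to carry a meaningful hue.
#' @return Logical positive-pixel mask.
#' @export
sabgal_positive_mask <- function(frame, cell_mask, hue_lo = 0.265,
                                 hue_hi = 0.58, s_min = 0.1) {
  stopifnot(inherits(frame, "color_frame"),
            all(dim(cell_mask) == dim(frame$pixels)[1:2]),
            hue_lo >= 0, hue_hi <= 1, hue_lo <= hue_hi)
  px <- frame$pixels
  hs <- rgb_to_hs(px[, , 1], px[, , 2], px[, , 3])
  # 1e-9 guards the closed bounds against floating-point representation only
  pos <- hs$h >= hue_lo - 1e-9 & hs$h <= hue_hi + 1e-9 & hs$s >= s_min
  matrix(pos, nrow(cell_mask), ncol(cell_mask)) & cell_mask
}

#' SAbGal positive-area fraction of one frame
#'
#' Composes [segment_cells_brightfield()] and [sabgal_positive_mask()]:
#' total positive area divided by total cell area. A frame with zero cell
#' area yields an NA fraction (flagged, not an error).
#'
#' @param frame A [color_frame()].
#' @param frame_id Identifier for the result row.
#' @param cell_mask Optional precomputed cell mask (skips segmentation).
#' @param ... Passed to the two component operations.
#' @return One-row data.frame: frame_id, cell_area_um2, positive_area_um2,
#'   positive_fraction.
#' @examples
#' im <- make_sabgal_image(sabgal_image_spec(stained_fraction = 1, seed = 3))
#' sabgal_fraction(im$rgb)$positive_fraction
#' @export
sabgal_fraction <- function(frame, frame_id = "frame", cell_mask = NULL, ...) {
  args <- list(...)
  seg_args <- args[names(args) %in% c("dilate_px", "erode_px", "min_object_um2")]
  pos_args <- args[names(args) %in% c("hue_lo", "hue_hi", "s_min")]
  if (is.null(cell_mask))
    cell_mask <- do.call(segment_cells_brightfield, c(list(frame), seg_args))
  pos <- do.call(sabgal_positive_mask, c(list(frame, cell_mask), pos_args))
  a <- pixel_area(frame)
  cell_area <- sum(cell_mask) * a
  positive_area <- sum(pos) * a
  data.frame(frame_id = frame_id, cell_area_um2 = cell_area,
             positive_area_um2 = positive_area,
             positive_fraction = if (cell_area > 0) positive_area / cell_area
                                 else NA_real_)
}

#' Pooled-area SAbGal fraction for a condition
#'
#' Aggregates per-frame results by dividing the summed positive area by the
#' summed cell area over all frames of a condition (pooled areas, not the
#' mean of per-frame fractions).
#'
#' @param results data.frame of rows from [sabgal_fraction()].
#' @param condition Label for the set.
#' @return One-row data.frame: condition, n_frames, cell_area_um2,
#'   positive_area_um2, positive_fraction.
#' @export
sabgal_condition <- function(results, condition = "condition") {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  cell <- sum(results$cell_area_um2)
  pos <- sum(results$positive_area_um2)
  data.frame(condition = condition, n_frames = nrow(results),
             cell_area_um2 = cell, positive_area_um2 = pos,
             positive_fraction = if (cell > 0) pos / cell else NA_real_)
}
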