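#' Specification for synthetic SAbGal brightfield color images
#'
#' Describes an RGB brightfield scene of cultured cells on a bright,
#' near-achromatic background. Each cell is a disc; within each cell a
#' contiguous sub-region covering \code{stained_fraction} of the cell's pixel
#' area is painted at \code{stained_hue}, and the remainder at
#' \code{unstained_hue}. Placing the stained hue inside the positive window
#' (0.265-0.58) and the unstained hue outside it yields an image whose true
#' positive-area fraction is known exactly by pixel counting.
#'
#' @param frame_shape Pixels (rows, cols).
#' @param pixel_size um per pixel.
#' @param cell_regions Optional list of logical masks (one per cell). When
#'   NULL, \code{n_cells} discs of radius \code{cell_radius} um are placed by
#'   rejection sampling.
#' @param n_cells,cell_radius Used only when \code{cell_regions} is NULL.
#' @param stained_fraction Fraction of each cell's area painted at
#'   \code{stained_hue}, in [0, 1].
#' @param stained_hue,unstained_hue HSV hues in [0, 1).
#' @param saturation Saturation of cell pixels, in (0, 1].
#' @param cell_value,background_value HSV value (brightness) of cell and
#'   background pixels.
#' @param noise_sd Gaussian RGB noise standard deviation (on the [0,1] scale).
#' @param seed Integer seed or NULL.
#' @return A list of class \code{sabgal_image_spec}.
#' @export
sabgal_image_spec <- function(frame_shape = c(256L, 256L), pixel_size = 1,
                              cell_regions = NULL, n_cells = 4L,
                              cell_radius = 30,
                              stained_fraction = 0.5,
                              stained_hue = 0.4, unstained_hue = 0.9,
                              saturation = 0.6, cell_value = 0.55,
                              background_value = 0.88,
                              noise_sd = 0.01, seed = NULL) {
  stopifnot(length(frame_shape) == 2L, pixel_size > 0,
            saturation >= 0, saturation <= 1, noise_sd >= 0)
  if (stained_fraction < 0 || stained_fraction > 1)
    stop("stained_fraction must lie in [0, 1]")
  if (stained_hue < 0 || stained_hue >= 1 || unstained_hue < 0 || unstained_hue >= 1)
    stop("hues must lie in [0, 1)")
  structure(list(frame_shape = as.integer(frame_shape), pixel_size = pixel_size,
                 cell_regions = cell_regions, n_cells = as.integer(n_cells),
                 cell_radius = cell_radius,
                 stained_fraction = stained_fraction,
                 stained_hue = stained_hue, unstained_hue = unstained_hue,
                 saturation = saturation, cell_value = cell_value,
                 background_value = background_value,
                 noise_sd = noise_sd, seed = seed),
            class = "sabgal_image_spec")
}

# order a region's pixels by distance from its leftmost pixel so that taking
# the first k gives a contiguous cap of exactly k pixels
contiguous_subset <- function(region_mask, k) {
  idx <- which(region_mask, arr.ind = TRUE)
  if (k <= 0L) return(idx[0, , drop = FALSE])
  seed_px <- idx[which.min(idx[, 2] * 1e6 + idx[, 1]), ]
  d2 <- (idx[, 1] - seed_px[1])^2 + (idx[, 2] - seed_px[2])^2
  idx[order(d2, idx[, 1], idx[, 2])[seq_len(min(k, nrow(idx)))], , drop = FALSE]
}

#' Generate a synthetic SAbGal-stained RGB image with exact truth
#'
#' Renders the scene described by a [sabgal_image_spec()] and returns the
#' 8-bit-quantized RGB frame together with the exact stained-pixel mask, the
#' cell mask, and the true positive-area fraction computed by direct pixel
#' counting on the painted masks.
#'
#' @param spec A \code{sabgal_image_spec}.
#' @return List with \code{rgb} (a [color_frame()]),
#'   \code{truth_positive_fraction}, \code{truth_cell_mask} and
#'   \code{truth_positive_mask}.
#' @examples
#' im <- make_sabgal_image(sabgal_image_spec(stained_fraction = 0.25, seed = 2))
#' im$truth_positive_fraction
#' @export
make_sabgal_image <- function(spec) {
  stopifnot(inherits(spec, "sabgal_image_spec"))
  shape <- spec$frame_shape
  with_seed_if(spec$seed, {
    regions <- spec$cell_regions
    if (is.null(regions)) {
      r_px <- spec$cell_radius / spec$pixel_size
      centers <- place_centers(spec$n_cells, shape, r_px + 2)
      regions <- lapply(seq_len(nrow(centers)), function(i)
        paint_discs(shape, centers[i, , drop = FALSE], r_px))
    }
    cell_mask <- Reduce(`|`, regions, matrix(FALSE, shape[1], shape[2]))
    positive_mask <- matrix(FALSE, shape[1], shape[2])
    for (reg in regions) {
      k <- round(spec$stained_fraction * sum(reg))
      sel <- contiguous_subset(reg, k)
      positive_mask[sel] <- TRUE
    }

    h <- matrix(0, shape[1], shape[2])
    s <- matrix(0.02, shape[1], shape[2])          # near-achromatic background
    v <- matrix(spec$background_value, shape[1], shape[2])
    h[cell_mask] <- spec$unstained_hue
    h[positive_mask] <- spec$stained_hue
    s[cell_mask] <- spec$saturation
    v[cell_mask] <- spec$cell_value
    rgb <- hsv_to_rgb(as.vector(h), as.vector(s), as.vector(v))
    px <- array(rgb, dim = c(shape[1], shape[2], 3))
    if (spec$noise_sd > 0)
      px <- px + stats::rnorm(length(px), 0, spec$noise_sd)
    px <- round(pmin(pmax(px, 0), 1) * 255) / 255   # 8-bit camera quantization

    n_cell <- sum(cell_mask)
    list(rgb = color_frame(px, spec$pixel_size),
         truth_positive_fraction = if (n_cell > 0) sum(positive_mask) / n_cell else NA_real_,
         truth_cell_mask = cell_mask,
         truth_positive_mask = positive_mask)
  })
}
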