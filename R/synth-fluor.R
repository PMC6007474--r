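#' Specification for synthetic immunofluorescence frames
#'
#' Describes a three-channel fluorescence scene: cells drawn as a nuclear disc
#' centred inside a larger cytoplasmic disc, placed without overlap by
#' rejection sampling. The DAPI channel is bright only over nuclei, the
#' phalloidin channel over the whole cell footprint, and the marker channel
#' carries distinct known mean intensities over the nuclear and cytoplasmic
#' compartments. Intensities are integer camera counts; Gaussian read noise is
#' added per pixel and the result rounded and clipped at zero.
#'
#' Defaults emulate a 256 x 256 um field imaged at 0.5 um/pixel with ~40
#' cells per field, marker levels 200 (nuclear) and 100 (cytoplasmic) over a
#' background of 10 counts.
#'
#' @param frame_shape Integer (rows, cols) in pixels.
#' @param pixel_size um per pixel.
#' @param n_cells Number of cells to place.
#' @param nuclear_radius,cytoplasm_radius Disc radii in um; nuclear must be
#'   smaller than cytoplasm.
#' @param nuclear_marker_mean,cytoplasm_marker_mean,background_mean Marker
#'   channel mean intensities (a.u.) over nuclei, cytoplasmic annuli and
#'   background.
#' @param dapi_level,phalloidin_level Foreground levels of the segmentation
#'   channels (a.u., above \code{background_mean}).
#' @param noise_sd Additive Gaussian noise standard deviation (a.u.), applied
#'   to all channels.
#' @param min_separation_um Minimum gap between cell footprints in um
#'   (subconfluent placement; keeps neighboring cells resolvable).
#' @param seed Integer seed fixing the output exactly, or NULL.
#' @return A list of class \code{fluor_frames_spec}.
#' @seealso [make_fluorescence_frames()]
#' @export
fluor_frames_spec <- function(frame_shape = c(512L, 512L), pixel_size = 0.5,
                              n_cells = 40L, nuclear_radius = 5,
                              cytoplasm_radius = 9,
                              nuclear_marker_mean = 200,
                              cytoplasm_marker_mean = 100,
                              background_mean = 10,
                              dapi_level = 200, phalloidin_level = 150,
                              noise_sd = 0, min_separation_um = 8,
                              seed = NULL) {
  stopifnot(length(frame_shape) == 2L, all(frame_shape >= 8),
            pixel_size > 0, n_cells >= 0,
            nuclear_radius > 0, cytoplasm_radius > 0)
  if (nuclear_radius >= cytoplasm_radius)
    stop("nuclear_radius must be smaller than cytoplasm_radius")
  means <- c(nuclear_marker_mean, cytoplasm_marker_mean, background_mean,
             dapi_level, phalloidin_level)
  if (any(means < 0) || noise_sd < 0)
    stop("intensity means and noise_sd must be non-negative")
  structure(list(frame_shape = as.integer(frame_shape), pixel_size = pixel_size,
                 n_cells = as.integer(n_cells),
                 nuclear_radius = nuclear_radius,
                 cytoplasm_radius = cytoplasm_radius,
                 nuclear_marker_mean = nuclear_marker_mean,
                 cytoplasm_marker_mean = cytoplasm_marker_mean,
                 background_mean = background_mean,
                 dapi_level = dapi_level, phalloidin_level = phalloidin_level,
                 noise_sd = noise_sd, min_separation_um = min_separation_um,
                 seed = seed),
            class = "fluor_frames_spec")
}

# place n disc centres (pixel units) with pairwise distance >=
# 2*radius_px + gap_px, margin from the border, by rejection sampling
place_centers <- function(n, shape, radius_px, gap_px = 0, max_attempts = 5000L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  margin <- radius_px + 1
  min_d2 <- (2 * radius_px + gap_px)^2
  if (2 * margin >= min(shape))
    stop("cells do not fit in the frame: radius too large for frame_shape")
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (a in seq_len(max_attempts)) {
    cand <- c(stats::runif(1, margin, shape[1] - margin),
              stats::runif(1, margin, shape[2] - margin))
    ok <- placed == 0L ||
      all((centers[seq_len(placed), 1] - cand[1])^2 +
          (centers[seq_len(placed), 2] - cand[2])^2 >= min_d2)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == n) return(centers)
    }
  }
  stop(sprintf(
    "could not place %d non-overlapping cells after %d attempts; the spec is over-dense",
    n, max_attempts))
}

# paint value 'level' over discs of radius radius_px at 'centers'; returns mask
paint_discs <- function(shape, centers, radius_px) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (nrow(centers) == 0L) return(mask)
  for (i in seq_len(nrow(centers))) {
    r0 <- max(1L, floor(centers[i, 1] - radius_px))
    r1 <- min(shape[1], ceiling(centers[i, 1] + radius_px))
    c0 <- max(1L, floor(centers[i, 2] - radius_px))
    c1 <- min(shape[2], ceiling(centers[i, 2] + radius_px))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, `+`)
    mask[rr, cc] <- mask[rr, cc] | (d2 <= radius_px^2)
  }
  mask
}

#' Generate synthetic DAPI / phalloidin / marker frames with exact truth
#'
#' Renders the scene described by a [fluor_frames_spec()]: non-overlapping
#' cells drawn as a nuclear disc inside a cytoplasmic disc. Returns the three
#' channels together with the exact ground-truth compartment masks and the
#' true compartment means, so segmentation and quantification can be scored
#' against known answers.
#'
#' @param spec A \code{fluor_frames_spec}.
#' @return A list with \code{dapi}, \code{phalloidin}, \code{marker}
#'   (each an [intensity_frame()]) and \code{truth}, a list holding the exact
#'   logical \code{nuclear} and \code{cytoplasmic} masks, the true means, and
#'   the cell centres (pixel coordinates).
#' @examples
#' fr <- make_fluorescence_frames(fluor_frames_spec(
#'   frame_shape = c(128, 128), n_cells = 4, seed = 1))
#' mean(fr$marker$pixels[fr$truth$nuclear])
#' @export
make_fluorescence_frames <- function(spec) {
  stopifnot(inherits(spec, "fluor_frames_spec"))
  shape <- spec$frame_shape
  nuc_px <- spec$nuclear_radius / spec$pixel_size
  cyt_px <- spec$cytoplasm_radius / spec$pixel_size
  with_seed_if(spec$seed, {
    centers <- place_centers(spec$n_cells, shape, cyt_px,
                             gap_px = spec$min_separation_um / spec$pixel_size)
    nuclear <- paint_discs(shape, centers, nuc_px)
    footprint <- paint_discs(shape, centers, cyt_px)
    cytoplasmic <- footprint & !nuclear

    render <- function(fg_levels) {
      img <- matrix(spec$background_mean, shape[1], shape[2])
      for (nm in names(fg_levels)) {
        m <- switch(nm, nuclear = nuclear, footprint = footprint,
                    cytoplasmic = cytoplasmic)
        img[m] <- fg_levels[[nm]]
      }
      if (spec$noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
      pmax(round(img), 0)
    }
    dapi <- render(list(nuclear = spec$dapi_level))
    phal <- render(list(footprint = spec$phalloidin_level))
    marker <- render(list(cytoplasmic = spec$cytoplasm_marker_mean,
                          nuclear = spec$nuclear_marker_mean))
    list(dapi = intensity_frame(dapi, spec$pixel_size),
         phalloidin = intensity_frame(phal, spec$pixel_size),
         marker = intensity_frame(marker, spec$pixel_size),
         truth = list(nuclear = nuclear, cytoplasmic = cytoplasmic,
                      nuclear_marker_mean = spec$nuclear_marker_mean,
                      cytoplasm_marker_mean = spec$cytoplasm_marker_mean,
                      centers = centers))
  })
}
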