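# Neurosphere detection and sizing in stitched whole-well brightfield images:
# well-rim active contour, reconstruction-based illumination correction plus
# homomorphic filtering, dynamic-range compression + CLAHE enhancement,
# local-entropy detection with watershed separation, and the physical
# diameter/eccentricity filter.

# bilinear sampling of matrix m at fractional (row, col) positions
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc + m[cbind(r1, c1)] * fr * fc
}

# circular moving average of a radius profile (the contour smoothness prior)
smooth_circular <- function(x, k = 15L, passes = 3L) {
  n <- length(x)
  w <- rep(1 / k, k)
  for (p in seq_len(passes)) {
    xp <- c(x[(n - (k %/% 2) + 1):n], x, x[1:(k %/% 2)])
    x <- stats::filter(xp, w, sides = 2)[(k %/% 2 + 1):(k %/% 2 + n)]
  }
  as.numeric(x)
}

#' Locate the well interior with a radial active contour on the rim gradient
#'
#' A closed contour of radial nodes, initialized as a circle inset from the
#' frame border, is attracted iteratively to the strongest image-gradient
#' response along each ray (the bright-interior/dark-exterior rim edge) and
#' regularized by circular smoothing of the radius profile. When no rim-like
#' gradient structure exists (the edge response never rises above the bulk
#' gradient level) the contour cannot converge and an error is raised; a
#' threshold-based fallback can be enabled instead.
#'
#' @param image An [intensity_frame()] of the stitched well.
#' @param n_rays Number of contour nodes (rays).
#' @param iterations Attraction/smoothing iterations.
#' @param fallback "none" (error when no rim is found) or "threshold"
#'   (Otsu threshold + largest filled component, used when the contour fails).
#' @return List of class \code{well_mask}: \code{interior} (logical),
#'   \code{contour} (n_rays x 2 matrix of row/col), \code{center},
#'   \code{radius_px} (mean radius).
#' @export
detect_well_interior <- function(image, n_rays = 360L, iterations = 5L,
                                 fallback = c("none", "threshold")) {
  stopifnot(inherits(image, "intensity_frame"))
  fallback <- match.arg(fallback)
  px <- image$pixels
  grad <- sobel_magnitude(as.matrix(EBImage::gblur(as_eb(px), sigma = 2)))
  theta <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  center <- dim(px) / 2
  r_max <- min(dim(px)) / 2 - 2

  rim_found <- FALSE
  radii <- rep(0.9 * r_max, n_rays)
  if (max(grad) > 0) {
    lo <- rep(0.5 * r_max, n_rays); hi <- rep(0.98 * r_max, n_rays)
    for (it in seq_len(iterations)) {
      peak <- numeric(n_rays); strength <- numeric(n_rays)
      for (i in seq_len(n_rays)) {
        rs <- seq(lo[i], hi[i], by = 1)
        g <- bilinear_sample(grad, center[1] + rs * cos(theta[i]),
                             center[2] + rs * sin(theta[i]))
        j <- which.max(g)
        peak[i] <- rs[j]; strength[i] <- g[j]
      }
      # a genuine rim stands far above the bulk gradient level
      if (stats::median(strength) < 5 * stats::median(grad) + 1e-12) break
      rim_found <- TRUE
      radii <- smooth_circular(peak)
      # recentre on the contour and tighten the search band around it
      pts <- cbind(center[1] + radii * cos(theta), center[2] + radii * sin(theta))
      center <- colMeans(pts)
      lo <- pmax(radii - 0.1 * r_max, 2)
      hi <- pmin(radii + 0.1 * r_max, r_max)
    }
  }

  if (!rim_found) {
    if (fallback == "none")
      stop("well rim not found: no dominant gradient ring for the active ",
           "contour to converge to (median edge response too weak)")
    thr <- otsu_threshold(px)
    mask <- as.matrix(EBImage::fillHull(as_eb((px > thr) * 1))) > 0.5
    lab <- label_mask(mask)
    if (max(lab) == 0) stop("threshold fallback found no well region")
    sizes <- tabulate(lab[lab > 0])
    interior <- lab == which.max(sizes)
    center <- colMeans(which(interior, arr.ind = TRUE))
    radius <- sqrt(sum(interior) / pi)
    contour <- cbind(center[1] + radius * cos(theta),
                     center[2] + radius * sin(theta))
    return(structure(list(interior = interior, contour = contour,
                          center = center, radius_px = radius),
                     class = "well_mask"))
  }

  rr <- matrix(seq_len(nrow(px)), nrow(px), ncol(px))
  cc <- matrix(seq_len(ncol(px)), nrow(px), ncol(px), byrow = TRUE)
  ang <- atan2(cc - center[2], rr - center[1]) %% (2 * pi)
  rad_at <- stats::approx(c(theta, 2 * pi), c(radii, radii[1]), xout = ang,
                          rule = 2)$y
  interior <- sqrt((rr - center[1])^2 + (cc - center[2])^2) <= rad_at
  contour <- cbind(center[1] + radii * cos(theta),
                   center[2] + radii * sin(theta))
  structure(list(interior = interior, contour = contour, center = center,
                 radius_px = mean(radii)),
            class = "well_mask")
}

#' Correct uneven illumination inside the well
#'
#' Estimates the slowly-varying illumination field by reconstruction-based
#' morphological filtering -- the average of the opening-by-reconstruction
#' (suppressing bright detail) and closing-by-reconstruction (suppressing dark
#' detail) with a structuring element larger than the largest expected sphere
#' -- divides it out (illumination is multiplicative), and then applies a
#' homomorphic filter (log-domain Gaussian high-pass) to attenuate any
#' residual multiplicative gradient. Output is restricted to the well
#' interior; exterior pixels are set to the interior mean so later windowed
#' filters see no artificial edge.
#'
#' @param image An [intensity_frame()].
#' @param well A \code{well_mask} from [detect_well_interior()].
#' @param se_diameter_um Structuring-element diameter in um; must exceed the
#'   largest expected sphere diameter.
#' @param gamma_low Homomorphic low-frequency gain in [0, 1] (1 = no
#'   attenuation).
#' @return An [intensity_frame()] of the corrected image.
#' @export
correct_illumination <- function(image, well, se_diameter_um = 320,
                                 gamma_low = 0.3) {
  stopifnot(inherits(image, "intensity_frame"), inherits(well, "well_mask"))
  if (!any(well$interior)) stop("well interior is empty")
  radius_px <- round(se_diameter_um / 2 / image$pixel_size)
  if (2 * radius_px + 1 > min(dim(image$pixels)))
    stop("structuring element (", 2 * radius_px + 1,
         " px) larger than the image")
  px <- image$pixels
  # extend interior values smoothly across the rim (normalized convolution),
  # so the background estimate sees no artificial edge at the well boundary
  w8 <- as.matrix(EBImage::gblur(as_eb(well$interior * 1), sigma = radius_px / 4,
                                 boundary = "replicate"))
  fill <- as.matrix(EBImage::gblur(as_eb(px * well$interior),
                                   sigma = radius_px / 4,
                                   boundary = "replicate")) / pmax(w8, 1e-6)
  f <- px; f[!well$interior] <- fill[!well$interior]
  # the background field is smooth at the structuring-element scale, so the
  # reconstruction runs on a downsampled image and the field is upsampled
  ds <- max(1L, floor(radius_px / 16))
  if (ds > 1L) {
    small <- as.matrix(EBImage::resize(as_eb(f), w = ceiling(nrow(f) / ds)))
    r_small <- max(2L, round(radius_px / ds))
    ob <- open_reconstruct(small, r_small)
    cb <- close_reconstruct(small, r_small)
    background <- as.matrix(EBImage::resize(as_eb((ob + cb) / 2),
                                            w = nrow(f), h = ncol(f)))
  } else {
    ob <- open_reconstruct(f, radius_px)
    cb <- close_reconstruct(f, radius_px)
    background <- (ob + cb) / 2
  }
  corrected <- f / pmax(background, 1e-6) * mean(background[well$interior])
  out <- homomorphic_filter(corrected, sigma_px = radius_px / 4,
                            gamma_low = gamma_low, roi = well$interior)
  out[!well$interior] <- mean(out[well$interior])
  intensity_frame(out, image$pixel_size)
}

#' Enhance sphere contrast before detection
#'
#' Rescales to [0, 1], applies a monotone log-domain dynamic-range
#' compression (which lifts low-contrast structure while preserving the local
#' ordering of intensities), then contrast-limited adaptive histogram
#' equalization (CLAHE), and rescales the result to [0, 1]. A constant image
#' is returned unchanged.
#'
#' @param image An [intensity_frame()] (typically illumination-corrected).
#' @param compression_k Strength of the log compression (0 disables).
#' @param clahe_tiles Number of CLAHE tiles per image side.
#' @param clahe_limit CLAHE contrast-limiting factor.
#' @return An [intensity_frame()] in [0, 1].
#' @export
enhance_contrast <- function(image, compression_k = 2, clahe_tiles = 8L,
                             clahe_limit = 4) {
  stopifnot(inherits(image, "intensity_frame"))
  px <- image$pixels
  rng <- range(px)
  if (rng[2] - rng[1] <= 1e-12) return(image)
  x <- (px - rng[1]) / (rng[2] - rng[1])
  if (compression_k > 0) x <- log1p(compression_k * x) / log1p(compression_k)
  y <- as.matrix(EBImage::clahe(as_eb(x), nx = clahe_tiles, ny = clahe_tiles,
                                limit = clahe_limit))
  intensity_frame(minmax_norm(y), image$pixel_size)
}

#' Detect sphere candidates by local entropy and watershed separation
#'
#' Computes local Shannon entropy in a sliding disc window (spheres read as
#' textured, high-entropy regions against a smooth background), thresholds
#' the entropy map by Otsu's method within the well interior, and splits
#' touching regions by watershed on the Gaussian-smoothed distance transform.
#' Regions touching the well contour are discarded (their geometry is
#' undefined). Returns unfiltered candidates in pixel units; apply
#' [filter_spheres()] for the physical sphere definition.
#'
#' The entropy response of a textured object extends roughly one window
#' radius beyond its true boundary, which would inflate every diameter; the
#' entropy map therefore only locates and separates objects, while each
#' region's geometry is measured on a tight texture-support mask (local
#' standard deviation in a small window, Otsu-thresholded, hole-filled, then
#' eroded by the window radius to cancel that window's own dilation).
#'
#' @param image Enhanced [intensity_frame()].
#' @param well A \code{well_mask}.
#' @param entropy_radius_px Disc window radius; default is half the minimum
#'   valid sphere diameter (25 um) in pixels.
#' @param entropy_bins Number of gray-level bins for the entropy estimate.
#' @param ws_sigma Gaussian sigma (px) smoothing the distance transform.
#' @param ws_tolerance Watershed minimum object depth (h-maxima suppression).
#' @param refine_radius_px Window radius of the boundary-refinement local-sd
#'   mask; 0 disables refinement and measures the raw entropy regions.
#' @return data.frame of candidates: label, centroid_row, centroid_col,
#'   area_px, eccentricity; the watershed label image is attached as
#'   attribute \code{labels}.
#' @export
detect_spheres <- function(image, well, entropy_radius_px = NULL,
                           entropy_bins = 32L, ws_sigma = 2,
                           ws_tolerance = 0.5, refine_radius_px = 1L) {
  stopifnot(inherits(image, "intensity_frame"), inherits(well, "well_mask"))
  if (!any(well$interior)) stop("well interior is empty")
  if (is.null(entropy_radius_px))
    entropy_radius_px <- max(3L, round(25 / image$pixel_size))
  px <- image$pixels
  px[!well$interior] <- stats::median(px[well$interior])
  ent <- local_entropy(px, entropy_radius_px, entropy_bins)
  thr <- otsu_threshold(ent, roi = well$interior)
  mask <- ent > thr & well$interior
  mask <- as.matrix(EBImage::fillHull(as_eb(mask * 1))) > 0.5
  mask <- drop_small_components(mask, max(9L, entropy_radius_px))

  empty <- data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = numeric(0),
                      eccentricity = numeric(0))
  if (!any(mask)) {
    attr(empty, "labels") <- matrix(0L, nrow(px), ncol(px))
    attr(empty, "pixel_size") <- image$pixel_size
    return(empty)
  }

  d <- EBImage::distmap(as_eb(mask * 1))
  ds <- as.matrix(EBImage::gblur(d, sigma = ws_sigma))
  ds[!mask] <- 0
  labels <- as.matrix(EBImage::watershed(EBImage::Image(ds),
                                         tolerance = ws_tolerance, ext = 1))
  labels[!mask] <- 0L

  # drop regions touching the well contour (partially imaged objects)
  edge <- well$interior &
    !(as.matrix(EBImage::erode(as_eb(well$interior * 1), disc_brush(2))) > 0.5)
  touching <- unique(labels[edge & labels > 0])
  if (length(touching)) labels[labels %in% touching] <- 0L

  if (refine_radius_px > 0 && any(labels > 0)) {
    tight <- local_sd(px, refine_radius_px)
    tmask <- tight > otsu_threshold(tight, roi = well$interior)
    tmask <- as.matrix(EBImage::fillHull(as_eb(tmask * 1))) > 0.5
    # the thresholded sd ramp crosses near the true boundary, so the mask
    # over-reaches by roughly radius - 1 px; erode by that amount
    er <- refine_radius_px - 1L
    if (er > 0)
      tmask <- as.matrix(EBImage::erode(as_eb(tmask * 1), disc_brush(er))) > 0.5
    labels[!tmask] <- 0L
  }

  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    attr(empty, "labels") <- labels
    attr(empty, "pixel_size") <- image$pixel_size
    return(empty)
  }
  # relabel consecutively for EBImage feature extraction
  relab <- labels
  relab[] <- match(labels, ids, nomatch = 0L)
  mom <- EBImage::computeFeatures.moment(EBImage::Image(relab))
  shp <- EBImage::computeFeatures.shape(EBImage::Image(relab))
  out <- data.frame(label = seq_along(ids),
                    centroid_row = mom[, "m.cx"],
                    centroid_col = mom[, "m.cy"],
                    area_px = shp[, "s.area"],
                    eccentricity = mom[, "m.eccentricity"])
  attr(out, "labels") <- relab
  attr(out, "pixel_size") <- image$pixel_size
  out
}

#' Apply the physical sphere definition to detected candidates
#'
#' Keeps candidates whose equivalent diameter exceeds \code{min_diameter_um}
#' and whose moment-ellipse eccentricity is below \code{max_eccentricity}
#' (both strict inequalities), and converts geometry to physical units.
#'
#' @param candidates data.frame from [detect_spheres()] (pixel geometry).
#' @param pixel_size um per pixel; taken from the candidates' attribute when
#'   omitted.
#' @param min_diameter_um Minimum equivalent diameter (default 50 um).
#' @param max_eccentricity Maximum eccentricity (default 0.8).
#' @return data.frame of sphere records: sphere_id, centroid_row,
#'   centroid_col, area_um2, equivalent_diameter_um, eccentricity.
#' @export
filter_spheres <- function(candidates, pixel_size = NULL,
                           min_diameter_um = 50, max_eccentricity = 0.8) {
  stopifnot(is.data.frame(candidates))
  if (is.null(pixel_size)) pixel_size <- attr(candidates, "pixel_size")
  if (is.null(pixel_size) || !is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size is required to apply the physical sphere definition")
  area_um2 <- candidates$area_px * pixel_size^2
  eqd <- 2 * sqrt(area_um2 / pi)
  keep <- eqd > min_diameter_um & candidates$eccentricity < max_eccentricity
  out <- data.frame(sphere_id = seq_len(sum(keep)),
                    centroid_row = candidates$centroid_row[keep],
                    centroid_col = candidates$centroid_col[keep],
                    area_um2 = area_um2[keep],
                    equivalent_diameter_um = eqd[keep],
                    eccentricity = candidates$eccentricity[keep])
  rownames(out) <- NULL
  out
}

#' Summarize the spheres of one well
#'
#' @param records data.frame from [filter_spheres()].
#' @param well_id Identifier.
#' @param large_area_um2 Threshold for the optional large-sphere count
#'   (default 1e5 um^2, strict).
#' @return List of class \code{sphere_summary}: well_id, sphere_count,
#'   areas (um^2 distribution), large_sphere_count.
#' @export
summarize_well <- function(records, well_id = "well", large_area_um2 = 1e5) {
  stopifnot(is.data.frame(records))
  structure(list(well_id = well_id, sphere_count = nrow(records),
                 areas = records$area_um2,
                 large_sphere_count = sum(records$area_um2 > large_area_um2)),
            class = "sphere_summary")
}

#' @export
print.sphere_summary <- function(x, ...) {
  cat(sprintf("<sphere_summary> well '%s': %d spheres (%d with area > 1e5 um^2)\n",
              x$well_id, x$sphere_count, x$large_sphere_count))
  if (x$sphere_count > 0)
    cat(sprintf("  area um^2: median %.0f, range [%.0f, %.0f]\n",
                stats::median(x$areas), min(x$areas), max(x$areas)))
  invisible(x)
}

#' Run the full sphere pipeline on one well image
#'
#' Composes [detect_well_interior()], [correct_illumination()],
#' [enhance_contrast()], [detect_spheres()], [filter_spheres()] and
#' [summarize_well()].
#'
#' @param image An [intensity_frame()] of the stitched well.
#' @param well_id Identifier.
#' @param config Optional [gq_config()] list overriding stage parameters.
#' @return List with \code{records}, \code{summary}, \code{well},
#'   \code{candidates}.
#' @export
analyze_well <- function(image, well_id = "well", config = gq_config()) {
  sp <- config$spheres
  well <- detect_well_interior(image, fallback = sp$well_fallback)
  corr <- correct_illumination(image, well, se_diameter_um = sp$se_diameter_um,
                               gamma_low = sp$gamma_low)
  enh <- enhance_contrast(corr, compression_k = sp$compression_k,
                          clahe_tiles = sp$clahe_tiles,
                          clahe_limit = sp$clahe_limit)
  cand <- detect_spheres(enh, well, entropy_radius_px = sp$entropy_radius_px,
                         entropy_bins = sp$entropy_bins,
                         ws_sigma = sp$ws_sigma,
                         ws_tolerance = sp$ws_tolerance,
                         refine_radius_px = sp$refine_radius_px)
  rec <- filter_spheres(cand, pixel_size = image$pixel_size,
                        min_diameter_um = sp$min_diameter_um,
                        max_eccentricity = sp$max_eccentricity)
  list(records = rec, summary = summarize_well(rec, well_id,
                                               large_area_um2 = sp$large_area_um2),
       well = well, candidates = cand)
}
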