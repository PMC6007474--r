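#' One synthetic neurosphere
#'
#' Geometry of a single rendered sphere: an ellipse with a stated equivalent
#' diameter and eccentricity, filled with bounded-amplitude high-frequency
#' texture so that local image entropy genuinely rises inside it.
#'
#' @param center (row, col) of the sphere centre in um from the image origin.
#' @param diameter Equivalent diameter in um (diameter of the circle with the
#'   ellipse's area), > 0.
#' @param eccentricity Moment-ellipse eccentricity in [0, 1).
#' @param orientation Major-axis angle in radians.
#' @param contrast Texture amplitude relative to the background level.
#' @return A list of class \code{sphere_spec}.
#' @export
sphere_spec <- function(center, diameter, eccentricity = 0, orientation = 0,
                        contrast = 0.25) {
  stopifnot(length(center) == 2L, diameter > 0,
            eccentricity >= 0, eccentricity < 1, contrast > 0)
  structure(list(center = as.numeric(center), diameter = diameter,
                 eccentricity = eccentricity, orientation = orientation,
                 contrast = contrast),
            class = "sphere_spec")
}

# semi-axes (um) of the ellipse with equivalent diameter d and eccentricity e
ellipse_axes <- function(diameter, eccentricity) {
  q <- (1 - eccentricity^2)^0.25
  c(a = (diameter / 2) / q, b = (diameter / 2) * q)
}

#' Specification for a synthetic whole-well brightfield image
#'
#' Describes a stitched grayscale well image: a bright circular well interior
#' on a dark exterior, containing textured elliptical spheres, degraded by a
#' multiplicative linear illumination gradient, radial vignetting and additive
#' Gaussian noise. Defaults render a scaled-down well (~1.1 mm virtual well at
#' 2.5 um/pixel) so whole-pipeline analyses run quickly at full fidelity of
#' the processing chain.
#'
#' @param frame_shape Pixels (rows, cols).
#' @param pixel_size um per pixel.
#' @param well_radius Well interior radius in um.
#' @param spheres List of [sphere_spec()] objects; all must fit inside the
#'   well disc.
#' @param illumination_gradient Multiplicative left-to-right linear gradient
#'   expressed as the max/min ratio (1 = flat; 2 doubles across the frame).
#' @param vignetting_strength Fractional radial fall-off at the frame corner.
#' @param background_level Well-interior background intensity in [0, 1].
#' @param noise_sd Additive Gaussian noise sd (on the [0, 1] scale).
#' @param seed Integer seed or NULL.
#' @return A list of class \code{well_image_spec}.
#' @export
well_image_spec <- function(frame_shape = c(480L, 480L), pixel_size = 2.5,
                            well_radius = 540, spheres = list(),
                            illumination_gradient = 1,
                            vignetting_strength = 0,
                            background_level = 0.55,
                            noise_sd = 0.01, seed = NULL) {
  stopifnot(length(frame_shape) == 2L, pixel_size > 0, well_radius > 0,
            illumination_gradient >= 1, vignetting_strength >= 0,
            vignetting_strength < 1, noise_sd >= 0)
  center_um <- c(frame_shape[1], frame_shape[2]) / 2 * pixel_size
  for (sp in spheres) {
    stopifnot(inherits(sp, "sphere_spec"))
    ax <- ellipse_axes(sp$diameter, sp$eccentricity)
    d <- sqrt(sum((sp$center - center_um)^2))
    if (d + ax["a"] > well_radius)
      stop("sphere extends outside the well disc: center too close to the rim")
  }
  structure(list(frame_shape = as.integer(frame_shape), pixel_size = pixel_size,
                 well_radius = well_radius, spheres = spheres,
                 illumination_gradient = illumination_gradient,
                 vignetting_strength = vignetting_strength,
                 background_level = background_level,
                 noise_sd = noise_sd, seed = seed),
            class = "well_image_spec")
}

# logical mask of an ellipse given centre (px), semi-axes (px), angle
paint_ellipse <- function(shape, center_px, a_px, b_px, theta) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dr <- rr - center_px[1]; dc <- cc - center_px[2]
  u <- dr * cos(theta) + dc * sin(theta)
  w <- -dr * sin(theta) + dc * cos(theta)
  (u / a_px)^2 + (w / b_px)^2 <= 1
}

#' Render a synthetic well image with analytically-known sphere records
#'
#' Renders the scene described by a [well_image_spec()]: spheres as textured
#' ellipses on a uniform interior, with the illumination gradient, vignetting
#' and noise applied multiplicatively/additively, quantized to 16-bit counts.
#' The truth table carries centroid, projected area, equivalent diameter and
#' eccentricity computed in closed form from the ellipse parameters.
#'
#' @param spec A \code{well_image_spec}.
#' @return List with \code{image} (an [intensity_frame()] of 16-bit counts),
#'   \code{truth} (data.frame: sphere_id, centroid_row, centroid_col in
#'   pixels, area_um2, equivalent_diameter_um, eccentricity) and
#'   \code{truth_well_mask} (logical interior disc).
#' @export
make_well_image <- function(spec) {
  stopifnot(inherits(spec, "well_image_spec"))
  shape <- spec$frame_shape
  ps <- spec$pixel_size
  center_px <- shape / 2
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  r2 <- (rr - center_px[1])^2 + (cc - center_px[2])^2
  well_mask <- r2 <= (spec$well_radius / ps)^2

  with_seed_if(spec$seed, {
    img <- matrix(0.08, shape[1], shape[2])           # dark well exterior
    img[well_mask] <- spec$background_level
    for (sp in spec$spheres) {
      ax <- ellipse_axes(sp$diameter, sp$eccentricity) / ps
      m <- paint_ellipse(shape, sp$center / ps, ax["a"], ax["b"], sp$orientation)
      n <- sum(m)
      # bounded-amplitude high-frequency texture raises local entropy
      img[m] <- spec$background_level *
        (1 + sp$contrast * stats::runif(n, -1, 1))
    }
    if (spec$illumination_gradient > 1) {
      g <- spec$illumination_gradient
      grad <- 1 + (g - 1) * (cc - 1) / (shape[2] - 1)
      img <- img * grad / mean(grad)
    }
    if (spec$vignetting_strength > 0) {
      rmax2 <- sum((shape / 2)^2)
      img <- img * (1 - spec$vignetting_strength * r2 / rmax2)
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    img <- round(pmin(pmax(img, 0), 1) * 65535)   # 16-bit camera counts

    truth <- if (length(spec$spheres) == 0L) {
      data.frame(sphere_id = integer(0), centroid_row = numeric(0),
                 centroid_col = numeric(0), area_um2 = numeric(0),
                 equivalent_diameter_um = numeric(0), eccentricity = numeric(0))
    } else {
      do.call(rbind, lapply(seq_along(spec$spheres), function(i) {
        sp <- spec$spheres[[i]]
        data.frame(sphere_id = i,
                   centroid_row = sp$center[1] / ps,
                   centroid_col = sp$center[2] / ps,
                   area_um2 = pi * (sp$diameter / 2)^2,
                   equivalent_diameter_um = sp$diameter,
                   eccentricity = sp$eccentricity)
      }))
    }
    list(image = intensity_frame(img, ps), truth = truth,
         truth_well_mask = well_mask)
  })
}
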