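#' Single-channel intensity frame
#'
#' The basic unit of grayscale microscopy input: a 2D grid of non-negative
#' pixel intensities (arbitrary units) together with the physical pixel size.
#'
#' @param pixels Numeric matrix of intensities (rows x cols).
#' @param pixel_size Physical pixel edge length in micrometres per pixel.
#' @return An object of class \code{intensity_frame}: a list with elements
#'   \code{pixels} and \code{pixel_size}.
#' @examples
#' f <- intensity_frame(matrix(runif(100), 10, 10), pixel_size = 0.5)
#' dim(f$pixels)
#' @export
intensity_frame <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/pixel)")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "intensity_frame")
}

#' RGB color frame
#'
#' A brightfield color image: an array of (R, G, B) triplets in [0, 1] with
#' the physical pixel size.
#'
#' @param pixels Numeric array of dimension (rows, cols, 3), values in [0, 1].
#' @param pixel_size Micrometres per pixel.
#' @return An object of class \code{color_frame}.
#' @export
color_frame <- function(pixels, pixel_size) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be a (rows, cols, 3) array")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("color values must lie in [0, 1]")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/pixel)")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "color_frame")
}

#' @export
print.intensity_frame <- function(x, ...) {
  cat(sprintf("<intensity_frame> %d x %d px @ %g um/px, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.color_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<color_frame> %d x %d px RGB @ %g um/px\n", d[1], d[2], x$pixel_size))
  invisible(x)
}

#' @export
dim.intensity_frame <- function(x) dim(x$pixels)

#' @export
dim.color_frame <- function(x) dim(x$pixels)[1:2]

# area of one pixel in um^2
pixel_area <- function(frame) frame$pixel_size^2
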