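# Raster I/O: 16-bit grayscale TIFF for intensity frames (with OME-XML
# physical-size metadata when present), 8-bit PNG/TIFF for RGB color frames.

# parse PhysicalSizeX="..." from an OME-XML image description, um units
ome_pixel_size <- function(description) {
  if (is.null(description) || !nzchar(description)) return(NULL)
  m <- regmatches(description,
                  regexec('PhysicalSizeX="([0-9.eE+-]+)"', description))[[1]]
  if (length(m) == 2L) as.numeric(m[2]) else NULL
}

#' Read a microscopy image from TIFF/OME-TIFF or PNG
#'
#' Grayscale images become an [intensity_frame()] (values scaled to 16-bit
#' counts, 0-65535), RGB images a [color_frame()] (values in [0, 1]). The
#' pixel size is taken from OME-XML \code{PhysicalSizeX} metadata when
#' present, else from the \code{pixel_size} argument or config; if neither is
#' available the read fails.
#'
#' @param path Image path (.tif/.tiff/.png).
#' @param pixel_size Fallback um/pixel when the file has no calibration.
#' @param config Optional [gq_config()] supplying \code{pixel_size}.
#' @return An \code{intensity_frame} or \code{color_frame}.
#' @export
read_image <- function(path, pixel_size = NULL, config = NULL) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  meta_ps <- NULL
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    meta_ps <- ome_pixel_size(attr(img, "description"))
  } else if (ext == "png") {
    img <- png::readPNG(path)
  } else stop("unsupported image format: .", ext)

  ps <- meta_ps
  if (is.null(ps)) ps <- pixel_size
  if (is.null(ps) && !is.null(config) && is.finite(config$pixel_size))
    ps <- config$pixel_size
  if (is.null(ps) || is.na(ps))
    stop("no pixel size: none in image metadata and none supplied via ",
         "argument or config")

  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    color_frame(array(img[, , 1:3], c(dim(img)[1:2], 3L)), ps)
  } else {
    if (length(dim(img)) == 3L) img <- img[, , 1]
    # plain matrix: readTIFF decorates its result with format attributes
    intensity_frame(matrix(round(img * 65535), nrow(img), ncol(img)), ps)
  }
}

# Minimal little-endian, single-strip, uncompressed 16-bit grayscale TIFF
# writer with an ImageDescription tag (tiff::writeTIFF cannot embed one).
# Read back with any libtiff-based reader.
write_tiff16 <- function(m, path, description = "") {
  h <- nrow(m); w <- ncol(m)
  data <- round(pmin(pmax(m, 0), 65535))
  desc <- c(charToRaw(description), as.raw(0))  # NUL-terminated ASCII
  data_off <- 8L
  data_len <- 2L * h * w
  desc_off <- data_off + data_len
  ifd_off <- desc_off + length(desc)
  if (ifd_off %% 2L == 1L) { desc <- c(desc, as.raw(0)); ifd_off <- ifd_off + 1L }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(as.integer(t(data)), con, size = 2, endian = "little")
  writeBin(desc, con)

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {           # SHORT packed left-aligned
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  tags <- list(
    list(256L, 3L, 1L, w),                     # ImageWidth
    list(257L, 3L, 1L, h),                     # ImageLength
    list(258L, 3L, 1L, 16L),                   # BitsPerSample
    list(259L, 3L, 1L, 1L),                    # Compression: none
    list(262L, 3L, 1L, 1L),                    # Photometric: BlackIsZero
    list(270L, 2L, length(desc), desc_off),    # ImageDescription
    list(273L, 4L, 1L, data_off),              # StripOffsets
    list(277L, 3L, 1L, 1L),                    # SamplesPerPixel
    list(278L, 3L, 1L, h),                     # RowsPerStrip
    list(279L, 4L, 1L, data_len))              # StripByteCounts
  writeBin(length(tags), con, size = 2, endian = "little")
  for (t in tags) do.call(entry, t)
  writeBin(0L, con, size = 4, endian = "little")  # next IFD: none
  invisible(path)
}

#' Write an intensity or color frame to disk
#'
#' Intensity frames are written as 16-bit grayscale TIFF with the pixel size
#' embedded as OME-style \code{PhysicalSizeX}/\code{PhysicalSizeY} metadata;
#' color frames as 8-bit PNG. Intensity values are interpreted as 16-bit
#' counts (0-65535), so integer-valued frames round-trip exactly.
#'
#' @param frame An [intensity_frame()] or [color_frame()].
#' @param path Output path (.tif/.tiff for intensity, .png for color).
#' @return \code{path}, invisibly.
#' @export
write_image <- function(frame, path) {
  if (inherits(frame, "intensity_frame")) {
    desc <- sprintf('PhysicalSizeX="%g" PhysicalSizeY="%g"',
                    frame$pixel_size, frame$pixel_size)
    write_tiff16(frame$pixels, path, description = desc)
  } else if (inherits(frame, "color_frame")) {
    png::writePNG(frame$pixels, path)
  } else stop("frame must be an intensity_frame or color_frame")
  invisible(path)
}

#' Write a result table as CSV
#'
#' All tabular outputs use explicit headers and fraction (not percent)
#' units.
#'
#' @param df data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_result_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
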