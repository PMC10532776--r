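#' Read an 8-bit raster image
#'
#' Decodes a PNG, TIFF or JPEG file into an H x W x 3 array with samples in
#' \[0, 255\] (red, green, blue order). Grayscale files are promoted to three
#' identical channels; an alpha channel, if present, is dropped.
#'
#' @param path path to the image file.
#' @return an H x W x 3 numeric array in \[0, 255\].
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) stop("path must be a single string")
  if (!file.exists(path)) .stop_io("cannot read image: file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) .stop_io("cannot decode '", path, "': ",
                                               conditionMessage(e)))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- array(a, dim = c(dim(a), 1L))
  }
  ## EBImage stores (x, y, channel); transpose to (row, col, channel)
  a <- aperm(a, c(2L, 1L, 3L))
  nc <- dim(a)[3L]
  if (nc == 1L) {
    a <- a[, , c(1L, 1L, 1L), drop = FALSE]
  } else if (nc == 2L) {          # gray + alpha
    a <- a[, , c(1L, 1L, 1L), drop = FALSE]
  } else if (nc > 3L) {           # drop alpha
    a <- a[, , 1:3, drop = FALSE]
  }
  ## source files are 8-bit; recover exact integer sample values
  out <- round(.clamp255(a * 255))
  as_color_image(out)
}

#' Write an 8-bit raster image
#'
#' Quantizes samples to integers (round-half-away from floating precision),
#' clamps to \[0, 255\] and encodes by file extension (.png, .tif/.tiff,
#' .jpg/.jpeg). This is the single point in the pipeline where planes are
#' re-quantized to 8 bits.
#'
#' @param img H x W x 3 array in \[0, 255\], or a gray plane matrix
#'   (written as grayscale).
#' @param path output file path; the extension selects the codec.
#' @param quality JPEG quality in \[1, 100\]; ignored for PNG/TIFF.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, quality = 95L) {
  if (is.matrix(img)) {
    plane <- .clamp255(round(as_gray_plane(img)))
    ei <- EBImage::Image(t(plane) / 255)
  } else {
    img <- as_color_image(img)
    q <- .clamp255(round(img))
    ei <- EBImage::Image(aperm(q, c(2L, 1L, 3L)) / 255, colormode = "Color")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) .stop_io("cannot write image: no such directory: ", dir)
  tryCatch(EBImage::writeImage(ei, path, quality = quality),
           error = function(e) .stop_io("cannot encode '", path, "': ",
                                        conditionMessage(e)))
  invisible(path)
}
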