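#' Read an RGB raster as an 8-bit array
#'
#' Reads a PNG (or TIFF) image and returns a numeric array of dimension
#' height x width x 3 with integer-valued entries in [0, 255]. Grayscale
#' images are replicated across the three channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array `[H, W, 3]`, values in 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format '.", ext, "' (supported: png, tif/tiff): ", path)
  )
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1L) x <- array(rep(x, 3L), dim = c(dim(x)[1:2], 3L))
  round(x * 255)
}

#' Write an 8-bit RGB array as PNG
#'
#' @param img Numeric array `[H, W, 3]` with values in 0..255.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  img <- pmin(pmax(round(img), 0), 255)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Resize an RGB raster with bilinear interpolation
#'
#' @param img Numeric array `[H, W, 3]`, 0..255.
#' @param size Target size as `c(width, height)` in pixels.
#' @param antialias Smooth before downsampling (default `TRUE`).
#' @return Numeric array `[height, width, 3]`, 0..255.
#' @export
resize_image <- function(img, size, antialias = TRUE) {
  stopifnot(length(size) == 2L, all(size >= 1))
  w <- as.integer(size[1]); h <- as.integer(size[2])
  if (nrow(img) == h && ncol(img) == w) return(img)
  # EBImage arrays are x-major: first dim is width
  e <- aperm(img / 255, c(2L, 1L, 3L))
  e <- EBImage::resize(EBImage::Image(e, colormode = "Color"), w = w, h = h,
                       filter = "bilinear", antialias = antialias)
  out <- aperm(EBImage::imageData(e), c(2L, 1L, 3L))
  pmin(pmax(round(out * 255), 0), 255)
}

#' Flip an image horizontally
#'
#' Mirrors the raster about its vertical axis. Applying it twice returns
#' the original array.
#'
#' @param img Numeric array `[H, W, C]` (any channel count) or matrix.
#' @return Array of identical shape.
#' @export
hflip_image <- function(img) {
  if (is.matrix(img)) return(img[, ncol(img):1, drop = FALSE])
  img[, dim(img)[2]:1, , drop = FALSE]
}
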