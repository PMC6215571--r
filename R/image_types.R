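#' Brightfield RGB image with physical pixel size
#'
#' The raw input of the pipeline: an 8-bit, 3-channel brightfield image
#' together with its pixel size in micrometres per pixel. Pixel values are
#' stored as numeric in `[0, 255]`.
#'
#' @param px numeric array `height x width x 3`, values in `[0, 255]`
#' @param pixel_size_um micrometres per pixel, finite and `> 0`
#' @return An object of class `rgb_image`: a list with elements `px` and
#'   `pixel_size_um`.
#' @export
rgb_image <- function(px, pixel_size_um) {
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L) {
    stop("px must be a height x width x 3 array", call. = FALSE)
  }
  if (anyNA(px) || min(px) < 0 || max(px) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single finite value > 0", call. = FALSE)
  }
  structure(list(px = px, pixel_size_um = pixel_size_um), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$px)
  cat(sprintf("<rgb_image> %d x %d px, %.4g um/px\n", d[1], d[2], x$pixel_size_um))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$px)

#' Read an 8-bit RGB TIFF or PNG as an [rgb_image()]
#'
#' @param path file path; format is chosen by extension (`.tif`/`.tiff` or
#'   `.png`)
#' @param pixel_size_um physical pixel size in micrometres per pixel (image
#'   files do not carry it reliably, so it is supplied by the caller)
#' @return An `rgb_image`.
#' @export
read_rgb_image <- function(path, pixel_size_um) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 3L && dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  rgb_image(round(raw * 255), pixel_size_um)
}

#' Write an [rgb_image()] to disk
#'
#' @param image an `rgb_image`
#' @param path output path ending in `.tif`/`.tiff` or `.png`
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- image$px / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    png = png::writePNG(arr, path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  invisible(path)
}
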