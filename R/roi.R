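#' Region-of-interest polygon
#'
#' The mucosal region of a section, delimited as a closed simple polygon in
#' pixel coordinates. The coordinate convention is x to the right, y down,
#' origin at the centre of the top-left pixel, so pixel `(row i, col j)`
#' (0-based) has its centre at `(x = j, y = i)`.
#'
#' @param x,y numeric vertex coordinates (at least 3 vertices, not repeated
#'   at the end; the polygon is implicitly closed)
#' @param pixel_size_um physical pixel size in micrometres per pixel
#' @param check_simple verify that the polygon has no self-intersections
#'   (O(n^2) in the number of edges; generators that construct provably
#'   simple polygons may skip it)
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(x, y, pixel_size_um = 1, check_simple = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L ||
      anyNA(x) || anyNA(y) || !all(is.finite(c(x, y)))) {
    stop("invalid ROI: need >= 3 finite vertices", call. = FALSE)
  }
  if (abs(polygon_signed_area(x, y)) <= 0) {
    stop("invalid ROI: enclosed area must be > 0", call. = FALSE)
  }
  if (check_simple && polygon_self_intersects(x, y)) {
    stop("invalid ROI: polygon is self-intersecting", call. = FALSE)
  }
  structure(list(x = x, y = y, pixel_size_um = pixel_size_um),
            class = "roi_polygon")
}

# shoelace; positive for counter-clockwise in a y-up frame
polygon_signed_area <- function(x, y) {
  j <- c(seq_along(x)[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# any two non-adjacent edges properly intersect?
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  j <- c(seq_len(n)[-1], 1L)
  x1 <- x; y1 <- y; x2 <- x[j]; y2 <- y[j]
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    if (i == 1L) ks <- ks[ks != n]  # edge n is adjacent to edge 1
    if (!length(ks)) next
    d1 <- cross(x2[i] - x1[i], y2[i] - y1[i], x1[ks] - x1[i], y1[ks] - y1[i])
    d2 <- cross(x2[i] - x1[i], y2[i] - y1[i], x2[ks] - x1[i], y2[ks] - y1[i])
    d3 <- cross(x2[ks] - x1[ks], y2[ks] - y1[ks], x1[i] - x1[ks], y1[i] - y1[ks])
    d4 <- cross(x2[ks] - x1[ks], y2[ks] - y1[ks], x2[i] - x1[ks], y2[i] - y1[ks])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' A pixel belongs to the ROI iff its centre lies inside the polygon by the
#' even-odd (crossing-number) rule: a horizontal ray from the pixel centre
#' crosses an odd number of polygon edges. Deterministic scanline
#' implementation; edges are treated half-open in y so vertices are never
#' double-counted.
#'
#' @param polygon an [roi_polygon()]
#' @param image_shape integer `c(height, width)` in pixels (the first two
#'   elements of `dim()` of the image array)
#' @return Logical `height x width` matrix. If the polygon extends beyond the
#'   image bounds it is clipped to the image, with a warning.
#' @export
rasterize_roi <- function(polygon, image_shape) {
  stopifnot(inherits(polygon, "roi_polygon"))
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  px <- polygon$x; py <- polygon$y
  if (min(px) < -0.5 || max(px) > w - 0.5 || min(py) < -0.5 || max(py) > h - 0.5) {
    warning("ROI polygon extends beyond the image bounds; clipping to image",
            call. = FALSE)
  }
  n <- length(px)
  j <- c(seq_len(n)[-1], 1L)
  x1 <- px; y1 <- py; x2 <- px[j]; y2 <- py[j]
  mask <- matrix(FALSE, nrow = h, ncol = w)
  xc <- 0:(w - 1L)
  rows <- 0:(h - 1L)
  rows <- rows[rows >= floor(min(py)) & rows <= ceiling(max(py))]
  for (yc in rows) {
    hit <- (y1 > yc) != (y2 > yc)
    if (!any(hit)) next
    xi <- x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    # centre is inside iff an odd number of crossings lie strictly to its right
    nright <- length(xi) - findInterval(xc, sort(xi))
    mask[yc + 1L, ] <- (nright %% 2L) == 1L
  }
  if (!any(mask)) {
    warning("ROI polygon covers no pixel centres: empty mask", call. = FALSE)
  }
  mask
}

#' Write / read an ROI polygon as JSON
#'
#' The JSON file holds the closed vertex list in pixel coordinates plus the
#' pixel size in micrometres.
#'
#' @param polygon an [roi_polygon()]
#' @param path JSON file path
#' @return `path` (write) or an `roi_polygon` (read).
#' @export
write_roi_json <- function(polygon, path) {
  stopifnot(inherits(polygon, "roi_polygon"))
  jsonlite::write_json(
    list(x = polygon$x, y = polygon$y, pixel_size_um = polygon$pixel_size_um),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_polygon(obj$x, obj$y, pixel_size_um = obj$pixel_size_um,
              check_simple = FALSE)
}
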