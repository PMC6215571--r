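#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert relation per channel:
#' `OD_c = -log10(max(I_c, eps) / I0_c)` with `eps = 1` grey level guarding
#' saturated black pixels, clamped at zero wherever the pixel is at or above
#' the background reference. Optical density is the space in which stains mix
#' additively, so all stain separation happens downstream of this transform.
#'
#' @param image an [rgb_image()]
#' @param background per-channel background (incident light) reference `I0`,
#'   each component in `(0, 255]`; defaults to pure white
#' @return An object of class `od_image`: list with `od` (same shape as the
#'   pixel array, non-negative) and `background`.
#' @export
rgb_to_od <- function(image, background = c(255, 255, 255)) {
  stopifnot(inherits(image, "rgb_image"))
  background <- as.numeric(background)
  if (length(background) == 1L) background <- rep(background, 3L)
  if (length(background) != 3L || !all(is.finite(background)) ||
      any(background <= 0) || any(background > 255)) {
    stop("invalid background reference: components must lie in (0, 255]",
         call. = FALSE)
  }
  d <- dim(image$px)
  i0 <- aperm(array(background, dim = c(3L, d[1], d[2])), c(2L, 3L, 1L))
  od <- -log10(pmax(image$px, 1) / i0)
  od[od < 0] <- 0
  structure(
    list(od = od, background = background, pixel_size_um = image$pixel_size_um),
    class = "od_image"
  )
}

#' Separate stains by color deconvolution
#'
#' Per pixel, solves the 3x3 linear system `od = t(M) %*% conc` where the rows
#' of `M` are the stain OD direction vectors, recovering the concentration of
#' each stain. Negative solutions (noise outside the stain cone) are clipped
#' to zero after solving.
#'
#' @param od an `od_image` from [rgb_to_od()]
#' @param stains a [stain_matrix()]
#' @return A list of three `height x width` concentration matrices:
#'   `hematoxylin`, `dab`, `residual` (arbitrary OD units, non-negative).
#' @export
deconvolve <- function(od, stains) {
  stopifnot(inherits(od, "od_image"))
  if (!inherits(stains, "stain_matrix")) {
    stop("stains must be a stain_matrix", call. = FALSE)
  }
  a <- stain_system_matrix(stains)
  ainv <- tryCatch(solve(a), error = function(e) {
    stop("degenerate stain basis: matrix is singular", call. = FALSE)
  })
  d <- dim(od$od)
  flat <- matrix(od$od, nrow = d[1] * d[2], ncol = 3L)  # pixels x channels
  conc <- flat %*% t(ainv)                              # pixels x stains
  conc[conc < 0] <- 0
  out <- lapply(1:3, function(k) matrix(conc[, k], nrow = d[1], ncol = d[2]))
  names(out) <- c("hematoxylin", "dab", "residual")
  out
}

#' Detect DAB-positive pixels
#'
#' @param dab_concentration `height x width` DAB concentration matrix from
#'   [deconvolve()]
#' @param od_threshold minimal DAB optical density counted as positive
#'   (`>= 0`); default 0.15, a common practice value
#' @return Logical matrix: `TRUE` where DAB concentration exceeds the
#'   threshold.
#' @export
detect_dab <- function(dab_concentration, od_threshold = 0.15) {
  stopifnot(is.matrix(dab_concentration))
  if (!is.numeric(od_threshold) || length(od_threshold) != 1L || od_threshold < 0) {
    stop("od_threshold must be a single value >= 0", call. = FALSE)
  }
  dab_concentration > od_threshold
}

#' Build the inverted 8-bit DAB intensity map
#'
#' Implements the convert-to-8-bit-then-invert step of the workflow so that
#' higher pixel value means higher expression: inside the mask the value is
#' `round(255 * min(concentration / scale_od, 1))`; outside the mask it is 0.
#' Rounding is round-half-to-even. Concentrations at or above `scale_od`
#' saturate at 255.
#'
#' @param dab_concentration DAB concentration matrix
#' @param mask logical DAB-positive mask (same shape)
#' @param scale_od optical density mapped to value 255 (`> 0`); default 1
#' @param pixel_size_um physical pixel size carried along for downstream
#'   morphometry
#' @return An object of class `dab_map`: list with `map` (integer matrix in
#'   `[0, 255]`), `mask` (logical matrix) and `pixel_size_um`. `map` is zero
#'   wherever `mask` is `FALSE`.
#' @export
to_inverted_8bit <- function(dab_concentration, mask, scale_od = 1,
                             pixel_size_um = 1) {
  stopifnot(is.matrix(dab_concentration), is.logical(mask),
            all(dim(mask) == dim(dab_concentration)))
  if (!is.numeric(scale_od) || length(scale_od) != 1L || scale_od <= 0) {
    stop("scale_od must be a single value > 0", call. = FALSE)
  }
  vals <- round(255 * pmin(dab_concentration / scale_od, 1))
  vals[!mask] <- 0
  structure(
    list(map = vals, mask = mask, pixel_size_um = pixel_size_um),
    class = "dab_map"
  )
}

#' Threshold window on the inverted 8-bit map
#'
#' @param low,high inclusive bounds on retained 8-bit values;
#'   `0 <= low < high <= 255`
#' @return An object of class `threshold_window`.
#' @export
threshold_window <- function(low = 5, high = 250) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || low < 0 || high > 255 || low >= high) {
    stop("threshold window requires 0 <= low < high <= 255", call. = FALSE)
  }
  structure(list(low = low, high = high), class = "threshold_window")
}

#' Apply a shared threshold window
#'
#' Filters unspecific too-high and/or too-low pixel values: map values below
#' `low` or above `high` are set to 0 and removed from the mask. The same
#' window object must be used for every image of one analysis run (the
#' pipeline enforces this by carrying a single window in its configuration).
#' Applying the same window twice is a no-op.
#'
#' @param map a `dab_map` from [to_inverted_8bit()]
#' @param window a [threshold_window()]
#' @return The filtered `dab_map`.
#' @export
apply_threshold_window <- function(map, window) {
  stopifnot(inherits(map, "dab_map"), inherits(window, "threshold_window"))
  drop <- map$mask & (map$map < window$low | map$map > window$high)
  map$mask <- map$mask & !drop
  map$map[!map$mask] <- 0
  map
}

#' Write a `dab_map` to disk
#'
#' The inverted intensity map is written as a single-channel 8-bit TIFF and
#' the mask as a 0/255 PNG.
#'
#' @param map a `dab_map`
#' @param map_path output TIFF path for the intensity map
#' @param mask_path optional output PNG path for the binary mask
#' @return `map_path`, invisibly.
#' @export
write_dab_map <- function(map, map_path, mask_path = NULL) {
  stopifnot(inherits(map, "dab_map"))
  tiff::writeTIFF(map$map / 255, map_path, bits.per.sample = 8L)
  if (!is.null(mask_path)) {
    png::writePNG(matrix(as.numeric(map$mask), nrow = nrow(map$mask)), mask_path)
  }
  invisible(map_path)
}
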