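#' Mucosal height measurements
#'
#' The per-section height measurements (micrometres) whose arithmetic mean is
#' the normalizer of the per-length expression statistic. Ten representative
#' sites is the working convention; other counts are accepted with a warning.
#'
#' @param heights numeric vector of heights in micrometres, all `> 0`
#' @return Object of class `mucosa_heights`: list with `heights` and `mean_um`.
#' @export
mucosa_heights <- function(heights) {
  heights <- as.numeric(heights)
  if (length(heights) == 0L) {
    stop("missing measurement: at least one mucosal height is required",
         call. = FALSE)
  }
  if (anyNA(heights) || any(!is.finite(heights)) || any(heights <= 0)) {
    stop("mucosal heights must all be finite and > 0", call. = FALSE)
  }
  if (length(heights) != 10L) {
    warning(sprintf("expected 10 height measurements, got %d", length(heights)),
            call. = FALSE)
  }
  structure(list(heights = heights, mean_um = mean(heights)),
            class = "mucosa_heights")
}

#' Mean mucosal height
#'
#' @param heights a [mucosa_heights()] object or a bare numeric vector
#' @return Arithmetic mean height in micrometres.
#' @export
mean_mucosal_height <- function(heights) {
  if (!inherits(heights, "mucosa_heights")) heights <- mucosa_heights(heights)
  heights$mean_um
}

#' Mucosal "length" inside the ROI
#'
#' The ROI area divided by the mean mucosal height. Working in physical
#' units: `length_um = (roi_area_px * pixel_size_um^2) / mean_height_um`.
#' Lengths in micrometres and pixels are interconvertible through the pixel
#' size, which is carried explicitly.
#'
#' @param roi_area_px ROI area as a pixel count (`> 0`)
#' @param pixel_size_um micrometres per pixel (`> 0`)
#' @param mean_height_um mean mucosal height in micrometres (`> 0`)
#' @return Length in micrometres.
#' @export
mucosa_length <- function(roi_area_px, pixel_size_um, mean_height_um) {
  if (!all(is.finite(c(roi_area_px, pixel_size_um, mean_height_um))) ||
      roi_area_px <= 0 || pixel_size_um <= 0 || mean_height_um <= 0) {
    stop("invalid normalizer: area, pixel size and mean height must be > 0",
         call. = FALSE)
  }
  (roi_area_px * pixel_size_um^2) / mean_height_um
}

#' Expression per micrometre of mucosa
#'
#' Total DAB intensity of the ROI divided by the mucosal "length" of the ROI.
#'
#' @param total_intensity total inverted 8-bit DAB intensity inside the ROI
#'   (arbitrary units, `>= 0`)
#' @param length_um mucosal length in micrometres (`> 0`)
#' @return Expression in arbitrary units per micrometre.
#' @export
expression_per_um <- function(total_intensity, length_um) {
  if (!is.finite(length_um) || length_um <= 0) {
    stop("invalid normalizer: length must be > 0", call. = FALSE)
  }
  if (!is.finite(total_intensity) || total_intensity < 0) {
    stop("total intensity must be finite and >= 0", call. = FALSE)
  }
  total_intensity / length_um
}

#' Percent DAB-positive area of the ROI
#'
#' The staining-intensity-robust alternative statistic: the percentage of ROI
#' pixels that are DAB-positive.
#'
#' @param dab_mask logical DAB-positive mask
#' @param roi_mask logical ROI mask of the same shape
#' @return Percentage in `[0, 100]`.
#' @export
percent_dab_area <- function(dab_mask, roi_mask) {
  stopifnot(is.logical(dab_mask), is.logical(roi_mask),
            all(dim(dab_mask) == dim(roi_mask)))
  n_roi <- sum(roi_mask)
  if (n_roi == 0L) stop("invalid ROI: empty ROI mask", call. = FALSE)
  100 * sum(dab_mask & roi_mask) / n_roi
}

#' Quantify one sample
#'
#' Runs the full single-sample workflow: RGB to optical density, stain
#' deconvolution, DAB detection, inverted 8-bit conversion, shared threshold
#' window, ROI rasterization, and the two summary statistics (expression per
#' micrometre and percent DAB-positive area). Every intermediate quantity is
#' recorded in the result for auditability.
#'
#' @param image an [rgb_image()]
#' @param roi an [roi_polygon()] delimiting the mucosa
#' @param heights mucosal height measurements ([mucosa_heights()] or numeric
#'   vector, micrometres)
#' @param config a [run_config()]; one shared configuration (in particular one
#'   threshold window) must be used for all images of an analysis run
#' @return Object of class `expression_result`: list with `roi_area_px`,
#'   `roi_area_um2`, `mean_height_um`, `length_um`, `total_intensity`,
#'   `expr_per_um`, `pct_area`, `n_dab_px`, `pixel_size_um`, plus the
#'   intermediate `dab_map` ROI-restricted summary.
#' @export
quantify_sample <- function(image, roi, heights, config = run_config()) {
  stopifnot(inherits(image, "rgb_image"), inherits(roi, "roi_polygon"))
  if (!inherits(heights, "mucosa_heights")) heights <- mucosa_heights(heights)
  if (!isTRUE(all.equal(image$pixel_size_um, roi$pixel_size_um))) {
    stop("pixel sizes of image and ROI disagree", call. = FALSE)
  }
  od <- rgb_to_od(image, background = config$background)
  conc <- deconvolve(od, config$stains)
  mask <- detect_dab(conc$dab, od_threshold = config$od_threshold)
  map <- to_inverted_8bit(conc$dab, mask, scale_od = config$scale_od,
                          pixel_size_um = image$pixel_size_um)
  map <- apply_threshold_window(map, config$window)

  roi_mask <- rasterize_roi(roi, dim(image$px)[1:2])
  roi_area_px <- sum(roi_mask)
  if (roi_area_px == 0L) stop("invalid ROI: empty after rasterization", call. = FALSE)

  psz <- image$pixel_size_um
  roi_area_um2 <- roi_area_px * psz^2
  mh <- heights$mean_um
  len <- mucosa_length(roi_area_px, psz, mh)
  total <- sum(map$map[roi_mask & map$mask])
  structure(list(
    roi_area_px     = roi_area_px,
    roi_area_um2    = roi_area_um2,
    mean_height_um  = mh,
    length_um       = len,
    total_intensity = total,
    expr_per_um     = expression_per_um(total, len),
    pct_area        = percent_dab_area(map$mask, roi_mask),
    n_dab_px        = sum(map$mask & roi_mask),
    pixel_size_um   = psz,
    window          = unlist(config$window[c("low", "high")])
  ), class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf(
    paste0("<expression_result> ROI %d px (%.6g um^2), mean height %.6g um,\n",
           "  length %.6g um, total intensity %.6g, expr/um %.6g, DAB area %.6g%%\n"),
    x$roi_area_px, x$roi_area_um2, x$mean_height_um,
    x$length_um, x$total_intensity, x$expr_per_um, x$pct_area))
  invisible(x)
}
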