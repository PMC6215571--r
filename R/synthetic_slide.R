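#' Specification of one synthetic brightfield slide
#'
#' Describes a simulated hematoxylin-counterstained mucosa band whose crypt
#' bases carry DAB-positive Paneth-cell-like granule clusters. All physical
#' defaults are a moderate-staining brightfield regime: granule peak DAB
#' optical density around 0.5 and a diffuse hematoxylin OD of 0.2, i.e. the
#' regime in which an 8-bit scanner image still supports faithful
#' Beer-Lambert quantification.
#'
#' @param width_px,height_px image size in pixels
#' @param pixel_size_um micrometres per pixel (`> 0`); default 1
#' @param mucosal_height_um mean mucosal height in micrometres; must not
#'   exceed `height_px * pixel_size_um`
#' @param height_jitter_sd_um per-site SD of the mucosal height profile
#' @param n_crypts number of crypts across the section
#' @param granules_per_crypt DAB granule clusters per crypt base
#' @param granule_radius_um granule cluster radius in micrometres
#' @param dab_od_mean,dab_od_sd mean and SD of the peak DAB optical density
#'   per granule; draws are truncated symmetrically at two SDs around the
#'   mean (and at 0), which keeps the mean exact and the chromogen within
#'   the OD range an 8-bit transmission image quantifies faithfully
#' @param hematoxylin_od diffuse hematoxylin optical density of the mucosa
#' @param background per-channel background RGB level (incident light);
#'   default pure white `c(255, 255, 255)`
#' @param noise_sd additive Gaussian RGB noise SD (grey levels, `>= 0`)
#' @param group slide group label, `"NEC-like"` or `"control-like"`
#' @param seed integer random seed; the whole slide is reproducible from it
#' @return Object of class `synthetic_slide_spec` (a validated list).
#' @export
synthetic_slide_spec <- function(width_px = 400L, height_px = 300L,
                                 pixel_size_um = 1,
                                 mucosal_height_um = 220,
                                 height_jitter_sd_um = 25,
                                 n_crypts = 8L, granules_per_crypt = 3L,
                                 granule_radius_um = 4,
                                 dab_od_mean = 0.4, dab_od_sd = 0.08,
                                 hematoxylin_od = 0.2,
                                 background = c(255, 255, 255),
                                 noise_sd = 2,
                                 group = c("control-like", "NEC-like"),
                                 seed = 1L) {
  group <- match.arg(group)
  spec <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um,
    mucosal_height_um = mucosal_height_um,
    height_jitter_sd_um = height_jitter_sd_um,
    n_crypts = as.integer(n_crypts),
    granules_per_crypt = as.integer(granules_per_crypt),
    granule_radius_um = granule_radius_um,
    dab_od_mean = dab_od_mean, dab_od_sd = dab_od_sd,
    hematoxylin_od = hematoxylin_od,
    background = as.numeric(background),
    noise_sd = noise_sd, group = group, seed = as.integer(seed)
  )
  validate_slide_spec(spec)
  class(spec) <- "synthetic_slide_spec"
  spec
}

validate_slide_spec <- function(spec) {
  pos <- c("width_px", "height_px", "pixel_size_um", "mucosal_height_um",
           "granule_radius_um")
  for (f in pos) {
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0) {
      stop("invalid simulation request: ", f, " must be > 0", call. = FALSE)
    }
  }
  nonneg <- c("height_jitter_sd_um", "dab_od_mean", "dab_od_sd",
              "hematoxylin_od", "noise_sd")
  for (f in nonneg) {
    if (!is.finite(spec[[f]]) || spec[[f]] < 0) {
      stop("invalid simulation request: ", f, " must be >= 0", call. = FALSE)
    }
  }
  if (spec$n_crypts < 0L || spec$granules_per_crypt < 0L) {
    stop("invalid simulation request: crypt/granule counts must be >= 0",
         call. = FALSE)
  }
  if (spec$mucosal_height_um > spec$height_px * spec$pixel_size_um) {
    stop("invalid simulation request: mucosal height exceeds image height",
         call. = FALSE)
  }
  if (length(spec$background) != 3L || any(spec$background <= 0) ||
      any(spec$background > 255)) {
    stop("invalid simulation request: background components must be in (0, 255]",
         call. = FALSE)
  }
  invisible(spec)
}

# evaluate RNG-dependent code under a local, seeded stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate one synthetic slide with ground truth
#'
#' Lays out a mucosa band of varying height anchored at the bottom of the
#' image, places Gaussian-profiled DAB granule disks at the crypt bases and a
#' diffuse hematoxylin field over the band, and composes the RGB image by
#' forward Beer-Lambert transmission `I_c = I0_c * 10^(-OD_c)` per channel,
#' where `OD_c` is the concentration-weighted sum of the stain vectors.
#' Gaussian RGB noise is then added, values are clipped to `[0, 255]` and
#' quantized (round-half-to-even). Granule centres snap to the pixel grid so
#' that peak optical densities are realized exactly at a pixel centre; the
#' granule profile is truncated at 1.2 sigma, keeping the DAB-positive
#' support crisp. Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_slide_spec()]
#' @return A list (slide bundle) with elements:
#'   * `image`: the [rgb_image()];
#'   * `roi`: the mucosa [roi_polygon()] (a staircase that rasterizes exactly
#'     to the simulated band);
#'   * `heights`: [mucosa_heights()] measured at ten evenly spaced sites;
#'   * `truth`: ground truth list with `dab_concentration` (matrix, OD units),
#'     `hematoxylin_concentration`, `dab_mask` (= concentration > 0),
#'     `roi_mask`, `total_dab_od` (sum of the concentration field over the
#'     ROI), `length_um`, `dab_od_per_um`, `area_fraction_pct`;
#'   * `spec`: the input spec.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  validate_slide_spec(spec)
  with_seed(spec$seed, {
    w <- spec$width_px; h <- spec$height_px; psz <- spec$pixel_size_um

    # mucosal height profile: ten jittered knots, linear in between
    sites <- round(seq(1, w, length.out = 10L))
    knots <- spec$mucosal_height_um +
      stats::rnorm(10L, 0, spec$height_jitter_sd_um)
    knots <- pmin(pmax(knots, 4 * psz), h * psz)
    prof <- stats::approx(sites, knots, xout = seq_len(w), rule = 2)$y
    n_col <- pmin(h, pmax(1L, as.integer(round(prof / psz))))
    top <- h - n_col                       # 0-based first mucosa row per column

    band <- matrix(FALSE, nrow = h, ncol = w)
    row0 <- matrix(0:(h - 1L), nrow = h, ncol = w)
    band[row0 >= matrix(top, nrow = h, ncol = w, byrow = TRUE)] <- TRUE

    # staircase polygon that rasterizes exactly to `band` (pixel-centre rule)
    vx <- c(rbind(0:(w - 1L) - 0.5, 0:(w - 1L) + 0.5), w - 0.5, -0.5)
    vy <- c(rbind(top - 0.5, top - 0.5), h - 0.5, h - 0.5)
    roi <- roi_polygon(vx, vy, pixel_size_um = psz, check_simple = FALSE)

    # stain concentration fields
    conc_h <- matrix(0, h, w); conc_h[band] <- spec$hematoxylin_od
    conc_d <- matrix(0, h, w)
    r_px <- spec$granule_radius_um / psz
    sigma <- r_px / 1.2
    if (spec$n_crypts > 0L && spec$granules_per_crypt > 0L) {
      crypt_x <- round(seq_len(spec$n_crypts) * w / (spec$n_crypts + 1))
      for (cx in crypt_x) {
        for (g in seq_len(spec$granules_per_crypt)) {
          gx <- as.integer(round(cx + stats::rnorm(1, 0, r_px)))
          gx <- min(max(gx, 0L), w - 1L)
          gy <- h - 1L - as.integer(ceiling(r_px)) - sample(0:2, 1L)
          gy <- min(max(gy, 0L), h - 1L)
          amp <- stats::rnorm(1, spec$dab_od_mean, spec$dab_od_sd)
          amp <- min(max(amp, spec$dab_od_mean - 2 * spec$dab_od_sd),
                     spec$dab_od_mean + 2 * spec$dab_od_sd)
          amp <- max(amp, 0)
          if (amp == 0) next
          rr <- as.integer(ceiling(r_px))
          ys <- max(0L, gy - rr):min(h - 1L, gy + rr)
          xs <- max(0L, gx - rr):min(w - 1L, gx + rr)
          d2 <- outer((ys - gy)^2, (xs - gx)^2, "+")
          prof_g <- amp * exp(-d2 / (2 * sigma^2))
          prof_g[d2 > r_px^2] <- 0
          # confluent granules merge: the chromogen layer saturates locally
          # rather than stacking, which keeps peak OD within the quantitative
          # range of an 8-bit transmission image
          conc_d[ys + 1L, xs + 1L] <- pmax(conc_d[ys + 1L, xs + 1L], prof_g)
        }
      }
    }
    conc_d[!band] <- 0

    # forward Beer-Lambert composition with the conventional H-DAB vectors
    stains <- default_hdab_stain_matrix()
    a <- stain_system_matrix(stains)        # channels x stains
    px <- array(0, dim = c(h, w, 3L))
    for (c3 in 1:3) {
      od_c <- a[c3, 1] * conc_h + a[c3, 2] * conc_d
      px[, , c3] <- spec$background[c3] * 10^(-od_c)
    }
    if (spec$noise_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, spec$noise_sd)
    }
    px <- round(pmin(pmax(px, 0), 255))
    image <- rgb_image(px, psz)

    heights <- mucosa_heights(n_col[sites] * psz)
    roi_area_um2 <- sum(band) * psz^2
    true_len <- roi_area_um2 / heights$mean_um
    dab_mask <- conc_d > 0
    total_od <- sum(conc_d[band])
    truth <- list(
      dab_concentration = conc_d,
      hematoxylin_concentration = conc_h,
      dab_mask = dab_mask,
      roi_mask = band,
      total_dab_od = total_od,
      length_um = true_len,
      dab_od_per_um = total_od / true_len,
      area_fraction_pct = 100 * sum(dab_mask & band) / sum(band)
    )
    list(image = image, roi = roi, heights = heights, truth = truth,
         spec = spec)
  })
}

#' Write a slide bundle to disk
#'
#' The image goes to an 8-bit RGB TIFF, the ROI to JSON, the heights to a
#' JSON array and the ground truth to a sidecar JSON (scalar summaries)
#' plus a 32-bit float single-channel TIFF of the DAB OD field.
#'
#' @param slide a bundle from [generate_slide()]
#' @param dir output directory (created if needed)
#' @param id sample identifier used as the file stem
#' @return Named character vector of the written paths, invisibly.
#' @export
write_slide_bundle <- function(slide, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, id)
  paths <- c(
    image = paste0(stem, ".tiff"),
    roi = paste0(stem, "_roi.json"),
    heights = paste0(stem, "_heights.json"),
    truth = paste0(stem, "_truth.json"),
    truth_od = paste0(stem, "_truth_od.tiff")
  )
  write_rgb_image(slide$image, paths[["image"]])
  write_roi_json(slide$roi, paths[["roi"]])
  jsonlite::write_json(slide$heights$heights, paths[["heights"]], digits = NA)
  tr <- slide$truth
  jsonlite::write_json(
    tr[c("total_dab_od", "length_um", "dab_od_per_um", "area_fraction_pct")],
    paths[["truth"]], digits = NA, auto_unbox = TRUE
  )
  od_max <- max(tr$dab_concentration, 1e-12)
  tiff::writeTIFF(tr$dab_concentration / od_max, paths[["truth_od"]],
                  bits.per.sample = 32L)
  invisible(paths)
}
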