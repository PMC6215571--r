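#' Analysis run configuration
#'
#' One configuration object is shared by every sample of an analysis run; in
#' particular the threshold window is set once per run and reused on each
#' image, which is what makes inverted-intensity totals comparable across
#' samples.
#'
#' @param stains a [stain_matrix()] or the string `"default-hdab"`
#' @param od_threshold minimal DAB optical density counted positive (default
#'   0.15)
#' @param scale_od optical density mapped to inverted 8-bit value 255
#'   (default 1)
#' @param window a [threshold_window()] (default `(5, 250)`)
#' @param background per-channel background reference (default white)
#' @param pixel_size_um default pixel size for images that do not carry one
#' @param ttest_variant `"pooled"` or `"welch"`
#' @param out_dir output directory for [run_analysis()]
#' @param seed integer seed recorded in the manifest
#' @return Object of class `run_config`.
#' @export
run_config <- function(stains = "default-hdab", od_threshold = 0.15,
                       scale_od = 1, window = threshold_window(5, 250),
                       background = c(255, 255, 255), pixel_size_um = 1,
                       ttest_variant = c("pooled", "welch"),
                       out_dir = ".", seed = 1L) {
  if (identical(stains, "default-hdab")) stains <- default_hdab_stain_matrix()
  if (!inherits(stains, "stain_matrix")) {
    stop("stains must be a stain_matrix or \"default-hdab\"", call. = FALSE)
  }
  if (!inherits(window, "threshold_window")) {
    stop("window must be a threshold_window", call. = FALSE)
  }
  if (!is.finite(od_threshold) || od_threshold < 0) {
    stop("od_threshold must be >= 0", call. = FALSE)
  }
  if (!is.finite(scale_od) || scale_od <= 0) {
    stop("scale_od must be > 0", call. = FALSE)
  }
  structure(list(
    stains = stains, od_threshold = od_threshold, scale_od = scale_od,
    window = window, background = as.numeric(background),
    pixel_size_um = pixel_size_um,
    ttest_variant = match.arg(ttest_variant),
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

config_snapshot <- function(config) {
  list(
    stains = unclass(config$stains),
    od_threshold = config$od_threshold,
    scale_od = config$scale_od,
    window = config$window[c("low", "high")],
    background = config$background,
    pixel_size_um = config$pixel_size_um,
    ttest_variant = config$ttest_variant,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dabquant"))
  )
}

#' Run the end-to-end analysis over a set of samples
#'
#' For every sample: load (or take) the image and ROI, quantify under the one
#' shared configuration, and append the result to the per-sample table.
#' Samples that fail to process are excluded with a recorded reason, never
#' dropped silently (mirroring the exclusion of sections with complete
#' mucosal erosion). If both groups are represented among the processed
#' samples, the group comparison report is computed. Outputs are written to
#' `config$out_dir`: `results.csv`, `report_tests.csv`,
#' `report_correlations.csv` and `manifest.json`. Bit-identical outputs for
#' identical inputs, configuration and seed.
#'
#' @param config a [run_config()]
#' @param samples a list; each element is a list with elements `image` (an
#'   [rgb_image()] or a TIFF/PNG path), `roi` (an [roi_polygon()] or an ROI
#'   JSON path), `heights` (numeric vector or [mucosa_heights()]), `record`
#'   (a [cohort_record()], optional but required for the group report), and
#'   optionally `id`
#' @return The manifest, invisibly: list with `config`, `samples`
#'   (per-sample status), `results` (data frame), `report` (or `NULL`), and
#'   output paths.
#' @export
run_analysis <- function(config, samples) {
  stopifnot(inherits(config, "run_config"))
  if (!is.list(samples) || length(samples) == 0L) {
    stop("no samples to analyse", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list(); status <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    id <- if (!is.null(s$id)) s$id else sprintf("sample%02d", i)
    res <- tryCatch({
      img <- if (inherits(s$image, "rgb_image")) s$image else
        read_rgb_image(s$image, config$pixel_size_um)
      roi <- if (inherits(s$roi, "roi_polygon")) s$roi else read_roi_json(s$roi)
      q <- quantify_sample(img, roi, s$heights, config)
      rec <- s$record
      data.frame(
        sample_id = id,
        group = if (!is.null(rec)) rec$group else NA_character_,
        tissue = if (!is.null(rec)) rec$tissue else NA_character_,
        ga_birth_weeks = if (!is.null(rec)) rec$ga_birth$weeks else NA_integer_,
        ga_birth_days = if (!is.null(rec)) rec$ga_birth$days else NA_integer_,
        birth_weight_g = if (!is.null(rec)) rec$birth_weight_g else NA_real_,
        postnatal_age_days = if (!is.null(rec)) rec$postnatal_age_days else NA_integer_,
        sex = if (!is.null(rec)) rec$sex else NA_character_,
        roi_area_px = q$roi_area_px, mean_height_um = q$mean_height_um,
        length_um = q$length_um, total_intensity = q$total_intensity,
        expr_per_um = q$expr_per_um, pct_area = q$pct_area,
        stringsAsFactors = FALSE
      )
    }, error = function(e) conditionMessage(e))
    if (is.data.frame(res)) {
      status[[id]] <- list(status = "ok")
      rows[[id]] <- res
    } else {
      status[[id]] <- list(status = "excluded", reason = res)
    }
  }
  if (length(rows) == 0L) stop("all samples failed to process", call. = FALSE)
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  report <- NULL
  if (all(c("NEC", "control") %in% results$group)) {
    report <- compare_groups(results, variant = config$ttest_variant)
  }

  paths <- c(results = file.path(config$out_dir, "results.csv"),
             tests = file.path(config$out_dir, "report_tests.csv"),
             correlations = file.path(config$out_dir, "report_correlations.csv"),
             manifest = file.path(config$out_dir, "manifest.json"))
  utils::write.csv(results, paths[["results"]], row.names = FALSE)
  if (!is.null(report)) {
    utils::write.csv(report$tests, paths[["tests"]], row.names = FALSE)
    utils::write.csv(report$correlations, paths[["correlations"]],
                     row.names = FALSE)
  }
  manifest <- list(config = config_snapshot(config), samples = status,
                   n_processed = nrow(results),
                   n_excluded = sum(vapply(status, function(x)
                     x$status == "excluded", logical(1))))
  jsonlite::write_json(manifest, paths[["manifest"]], digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(config = config, samples = status, results = results,
                 report = report, paths = paths))
}

#' Packaged validation experiments
#'
#' Executes the package's validation battery and returns a pass/fail
#' summary: stain-separation oracle agreement, noise-free round trip,
#' tiling additivity, mucosal-height sensitivity, parameter recovery
#' (Spearman of measured expression per micrometre against true DAB OD per
#' micrometre over slides spanning a wide staining range), t-test type-I
#' calibration under the null, and group-difference direction under a strong
#' simulated effect.
#'
#' @param seed integer seed driving every random draw
#' @param reps_type1 Monte-Carlo replicates for the type-I calibration
#' @param n_cohorts cohorts for the direction experiment
#' @param n_recovery slides for the parameter-recovery experiment
#' @param stains stain matrix used throughout (a deliberately wrong matrix
#'   makes the round-trip check fail, a useful negative control)
#' @return Data frame with columns `check`, `value`, `criterion`, `pass`.
#' @export
run_validation_suite <- function(seed = 1L, reps_type1 = 2000L,
                                 n_cohorts = 50L, n_recovery = 24L,
                                 stains = default_hdab_stain_matrix()) {
  config <- run_config(stains = stains)
  res <- list()

  # whole-image deconvolution vs per-pixel solves
  dec <- with_seed(seed, {
    a <- stain_system_matrix(stains)
    err <- 0
    for (r in 1:5) {
      od_arr <- array(stats::runif(8 * 8 * 3, 0, 1), dim = c(8, 8, 3))
      od <- structure(list(od = od_arr, background = c(255, 255, 255)),
                      class = "od_image")
      conc <- deconvolve(od, stains)
      for (i in 1:8) for (j in 1:8) {
        ref <- pmax(solve(a, od_arr[i, j, ]), 0)
        got <- c(conc$hematoxylin[i, j], conc$dab[i, j], conc$residual[i, j])
        err <- max(err, max(abs(ref - got)))
      }
    }
    err
  })
  res$deconvolution_oracle <- list(value = dec, criterion = "< 1e-9",
                                   pass = dec < 1e-9)

  # noise-free round trip through 8-bit quantization
  spec <- synthetic_slide_spec(noise_sd = 0, seed = seed)
  sl <- generate_slide(spec)
  conc <- deconvolve(rgb_to_od(sl$image), stains)
  rt <- max(abs(conc$dab - sl$truth$dab_concentration),
            abs(conc$hematoxylin - sl$truth$hematoxylin_concentration))
  res$round_trip_max_od_error <- list(value = rt, criterion = "< 1e-2",
                                      pass = rt < 1e-2)

  # tiling additivity of the per-um statistic
  q_all <- quantify_sample(sl$image, sl$roi, sl$heights, config)
  halves <- split_roi_columns(sl, config)
  tile_err <- abs((halves$total1 + halves$total2) / (halves$len1 + halves$len2) -
                  q_all$expr_per_um) / max(q_all$expr_per_um, 1e-12)
  res$tiling_additivity_rel_error <- list(value = tile_err,
                                          criterion = "< 1e-9",
                                          pass = tile_err < 1e-9)

  # doubling the mean height doubles expression per um
  q2 <- quantify_sample(sl$image, sl$roi,
                        mucosa_heights(sl$heights$heights * 2), config)
  ratio <- q2$expr_per_um / q_all$expr_per_um
  res$height_doubling_ratio <- list(value = ratio, criterion = "= 2 (1e-9)",
                                    pass = abs(ratio - 2) < 1e-9)

  # parameter recovery across a wide staining range
  rec <- recovery_experiment(n_recovery, seed = seed + 1L, config = config)
  res$recovery_spearman <- list(value = rec, criterion = ">= 0.9",
                                pass = rec >= 0.9)

  # type-I calibration of the pooled t-test at n = 8 vs 4
  t1 <- type1_error_rate(reps_type1, n_a = 8L, n_b = 4L, seed = seed + 2L)
  tol <- 3 * sqrt(0.05 * 0.95 / reps_type1)
  res$type1_error_rate <- list(
    value = t1, criterion = sprintf("0.05 +/- %.3g", tol),
    pass = abs(t1 - 0.05) <= tol)

  # direction of the group difference under a strong effect
  dirr <- effect_direction_rate(n_cohorts, effect_size = 0.6,
                                seed = seed + 3L, config = config)
  res$effect_direction_rate <- list(value = dirr, criterion = ">= 0.95",
                                    pass = dirr >= 0.95)

  data.frame(
    check = names(res),
    value = vapply(res, function(x) x$value, numeric(1)),
    criterion = vapply(res, function(x) x$criterion, character(1)),
    pass = vapply(res, function(x) x$pass, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# quantify the left and right halves of a generated slide's band separately
split_roi_columns <- function(slide, config) {
  h <- dim(slide$image$px)[1]; w <- dim(slide$image$px)[2]
  band <- slide$truth$roi_mask
  img <- slide$image
  od <- rgb_to_od(img, background = config$background)
  conc <- deconvolve(od, config$stains)
  mask <- detect_dab(conc$dab, config$od_threshold)
  map <- apply_threshold_window(
    to_inverted_8bit(conc$dab, mask, config$scale_od, img$pixel_size_um),
    config$window)
  mid <- w %/% 2
  left <- band; left[, (mid + 1):w] <- FALSE
  right <- band; right[, 1:mid] <- FALSE
  psz <- img$pixel_size_um
  mh <- slide$heights$mean_um
  list(
    total1 = sum(map$map[left & map$mask]),
    total2 = sum(map$map[right & map$mask]),
    len1 = mucosa_length(sum(left), psz, mh),
    len2 = mucosa_length(sum(right), psz, mh)
  )
}

# slides spanning a wide (>= 10x) range of true DAB OD per um; Spearman of
# measured expression per um against the ground-truth DAB OD per um
recovery_experiment <- function(n_slides = 24L, seed = 1L,
                                config = run_config()) {
  grid <- expand.grid(nc = c(2L, 5L, 9L, 14L), od = c(0.2, 0.35, 0.55))
  grid <- grid[rep(seq_len(nrow(grid)), length.out = n_slides), ]
  truth <- meas <- numeric(n_slides)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_slides))
  for (i in seq_len(n_slides)) {
    spec <- synthetic_slide_spec(
      n_crypts = grid$nc[i], dab_od_mean = grid$od[i],
      dab_od_sd = 0.05, noise_sd = 0, seed = seeds[i])
    sl <- generate_slide(spec)
    q <- quantify_sample(sl$image, sl$roi, sl$heights, config)
    truth[i] <- sl$truth$dab_od_per_um
    meas[i] <- q$expr_per_um
  }
  stats::cor(truth, meas, method = "spearman")
}

# pooled t-test rejection rate at alpha = 0.05 under the null
type1_error_rate <- function(reps = 10000L, n_a = 8L, n_b = 4L, seed = 1L,
                             alpha = 0.05) {
  with_seed(seed, {
    rej <- 0L
    for (r in seq_len(reps)) {
      p <- two_sample_ttest(stats::rnorm(n_a), stats::rnorm(n_b))$p
      if (p < alpha) rej <- rej + 1L
    }
    rej / reps
  })
}

# fraction of simulated cohorts in which the NEC-like group mean of measured
# expression per um falls below the control-like group mean
effect_direction_rate <- function(n_cohorts = 200L, effect_size = 0.6,
                                  seed = 1L, config = run_config(),
                                  base_spec = validation_slide_spec()) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_cohorts))
  below <- 0L
  for (k in seq_len(n_cohorts)) {
    coh <- generate_cohort(8L, 4L, effect_size = effect_size,
                           base_spec = base_spec, seed = seeds[k])
    tab <- cohort_results_table(coh, config)
    m <- tapply(tab$expr_per_um, tab$group, mean)
    if (m[["NEC"]] < m[["control"]]) below <- below + 1L
  }
  below / n_cohorts
}

#' Reduced-size slide specification for Monte-Carlo validation
#'
#' Same staining regime as the default slide but a quarter of the pixels,
#' the problem size the package uses for its repeated-cohort calibration
#' experiments.
#'
#' @param ... overrides passed to [synthetic_slide_spec()]
#' @return A [synthetic_slide_spec()].
#' @export
validation_slide_spec <- function(...) {
  args <- list(width_px = 160L, height_px = 120L, mucosal_height_um = 80,
               height_jitter_sd_um = 10, n_crypts = 4L,
               granules_per_crypt = 2L, noise_sd = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_slide_spec, args)
}
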