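#' Per-patient cohort record
#'
#' Metadata schema of the study cohort table: group, tissue origin,
#' gestational age at birth, birth weight, postnatal age at surgery, sex.
#'
#' @param patient_id identifier string
#' @param group `"NEC"` or `"control"`
#' @param tissue `"ileum"`, `"jejunum"` or `"colon"`
#' @param ga_birth a [gestational_age()] at birth
#' @param birth_weight_g birth weight in grams (`> 0`)
#' @param postnatal_age_days postnatal age at surgery in days (`>= 0`)
#' @param sex `"male"` or `"female"`
#' @return Object of class `cohort_record`.
#' @export
cohort_record <- function(patient_id, group, tissue, ga_birth, birth_weight_g,
                          postnatal_age_days, sex) {
  group <- match.arg(group, c("NEC", "control"))
  tissue <- match.arg(tissue, c("ileum", "jejunum", "colon"))
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(inherits(ga_birth, "gestational_age"))
  if (!is.finite(birth_weight_g) || birth_weight_g <= 0) {
    stop("birth weight must be > 0", call. = FALSE)
  }
  if (!is.finite(postnatal_age_days) || postnatal_age_days < 0) {
    stop("postnatal age must be >= 0", call. = FALSE)
  }
  structure(list(
    patient_id = as.character(patient_id), group = group, tissue = tissue,
    ga_birth = ga_birth, birth_weight_g = birth_weight_g,
    postnatal_age_days = as.integer(postnatal_age_days), sex = sex
  ), class = "cohort_record")
}

#' Generate a synthetic cohort of slides with records
#'
#' Emulates the study design (by default 8 NEC vs 4 controls): control-like
#' slides use the base DAB optical density, NEC-like slides scale the DAB OD
#' mean by `(1 - effect_size)`. Mucosal heights and gestational ages are
#' drawn per subject: gestational age at birth uniform over 23-40 completed
#' weeks, postnatal age at surgery uniform over 4-50 days, birth weight
#' roughly linear in gestational age, tissue predominantly ileum.
#'
#' @param n_nec,n_control group sizes (`>= 1`)
#' @param effect_size relative DAB reduction in the NEC-like group, in `[0, 1)`
#' @param base_spec a [synthetic_slide_spec()] providing all slide parameters
#' @param seed integer seed for the cohort draw; per-slide seeds are derived
#'   from it
#' @return List of `n_nec + n_control` bundles, each a list with elements
#'   `slide` (a [generate_slide()] bundle) and `record` (a [cohort_record()]).
#' @export
generate_cohort <- function(n_nec = 8L, n_control = 4L, effect_size = 0,
                            base_spec = synthetic_slide_spec(), seed = 1L) {
  stopifnot(inherits(base_spec, "synthetic_slide_spec"))
  if (n_nec < 1L || n_control < 1L) {
    stop("each group needs at least one subject", call. = FALSE)
  }
  if (!is.finite(effect_size) || effect_size < 0 || effect_size >= 1) {
    stop("effect_size must lie in [0, 1)", call. = FALSE)
  }
  n <- n_nec + n_control
  groups <- rep(c("NEC", "control"), c(n_nec, n_control))
  max_h <- base_spec$height_px * base_spec$pixel_size_um
  with_seed(seed, {
    slide_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      spec <- base_spec
      spec$seed <- slide_seeds[i]
      spec$group <- if (groups[i] == "NEC") "NEC-like" else "control-like"
      h <- stats::rnorm(1, base_spec$mucosal_height_um,
                        0.2 * base_spec$mucosal_height_um)
      spec$mucosal_height_um <- min(max(h, 8 * base_spec$pixel_size_um),
                                    0.95 * max_h)
      if (groups[i] == "NEC") {
        spec$dab_od_mean <- base_spec$dab_od_mean * (1 - effect_size)
      }
      ga <- gestational_age(sample(23:40, 1L), sample(0:6, 1L))
      bw <- max(round(stats::rnorm(1, 185 * ga_to_decimal_weeks(ga) - 3650, 250)), 400)
      rec <- cohort_record(
        patient_id = sprintf("S%02d", i),
        group = groups[i],
        tissue = sample(c("ileum", "jejunum", "colon"), 1L,
                        prob = c(10, 1, 1)),
        ga_birth = ga,
        birth_weight_g = bw,
        postnatal_age_days = sample(4:50, 1L),
        sex = sample(c("male", "female"), 1L)
      )
      list(slide = generate_slide(spec), record = rec)
    })
  })
}

#' Tabulate a synthetic cohort: records plus measured and true statistics
#'
#' Quantifies every slide of a [generate_cohort()] output under one shared
#' configuration and binds the per-patient metadata, the measured statistics
#' and the simulator ground truth into one data frame.
#'
#' @param cohort output of [generate_cohort()]
#' @param config a [run_config()]
#' @return A data frame with one row per subject: `patient_id`, `group`,
#'   `tissue`, `ga_birth_weeks`, `ga_birth_days`, `birth_weight_g`,
#'   `postnatal_age_days`, `sex`, `roi_area_px`, `mean_height_um`,
#'   `length_um`, `total_intensity`, `expr_per_um`, `pct_area`,
#'   `true_dab_od_per_um`, `true_area_fraction_pct`.
#' @export
cohort_results_table <- function(cohort, config = run_config()) {
  rows <- lapply(cohort, function(b) {
    r <- b$record
    q <- quantify_sample(b$slide$image, b$slide$roi, b$slide$heights, config)
    data.frame(
      patient_id = r$patient_id, group = r$group, tissue = r$tissue,
      ga_birth_weeks = r$ga_birth$weeks, ga_birth_days = r$ga_birth$days,
      birth_weight_g = r$birth_weight_g,
      postnatal_age_days = r$postnatal_age_days, sex = r$sex,
      roi_area_px = q$roi_area_px, mean_height_um = q$mean_height_um,
      length_um = q$length_um, total_intensity = q$total_intensity,
      expr_per_um = q$expr_per_um, pct_area = q$pct_area,
      true_dab_od_per_um = b$slide$truth$dab_od_per_um,
      true_area_fraction_pct = b$slide$truth$area_fraction_pct,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a cohort table to CSV
#'
#' Columns: `patient_id`, `group`, `tissue`, `ga_birth_weeks`,
#' `ga_birth_days`, `birth_weight_g`, `postnatal_age_days`, `sex`, plus any
#' further columns present.
#'
#' @param tab data frame as from [cohort_results_table()]
#' @param path CSV output path
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
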