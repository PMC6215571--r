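#' Two-sample t-test between groups
#'
#' Standard two-sided two-sample t-test, pooled-variance by default (the
#' conventional spreadsheet two-sample choice), Welch's unequal-variance
#' variant available. Degenerate input with zero variance in both groups and
#' equal means is reported as `t = 0`, `p = 1` and flagged.
#'
#' @param a,b numeric value vectors, each of length `>= 2` with finite values
#' @param variant `"pooled"` (equal variance) or `"welch"`
#' @return Object of class `group_comparison`: list with `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `n_a`, `n_b`, `t`, `df`, `p`, `variant`, `degenerate`.
#' @examples
#' two_sample_ttest(c(1, 2, 3, 4), c(2, 3, 4, 5))  # t = -1.095, df = 6
#' @export
two_sample_ttest <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient data: each group needs at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("insufficient data: all values must be finite", call. = FALSE)
  }
  out <- list(mean_a = mean(a), mean_b = mean(b),
              sd_a = stats::sd(a), sd_b = stats::sd(b),
              n_a = length(a), n_b = length(b),
              variant = variant, degenerate = FALSE)
  if (out$sd_a == 0 && out$sd_b == 0 && out$mean_a == out$mean_b) {
    out$t <- 0
    out$df <- length(a) + length(b) - 2
    out$p <- 1
    out$degenerate <- TRUE
    warning("zero variance in both groups with equal means: p = 1 by convention",
            call. = FALSE)
  } else {
    tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s t-test: t = %.6g, df = %.6g, p = %.6g\n  group a: mean %.6g (sd %.6g, n %d); group b: mean %.6g (sd %.6g, n %d)\n",
    x$variant, x$t, x$df, x$p,
    x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' Sample Pearson correlation
#'
#' @param x,y numeric vectors of equal length `>= 3` with non-zero variance
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with at least 3 observations", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: a variable has zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Bundled NEC/control cohort table
#'
#' The 12-infant study population (8 NEC, 4 dysmotility controls) with
#' gestational age at birth and at surgery (completed weeks + days), birth
#' weight, postnatal age at surgery and sex. Serves as the fixture for the
#' gestational-age arithmetic worked examples.
#'
#' @return A data frame with columns `patient_id`, `group`, `tissue`,
#'   `ga_birth_weeks`, `ga_birth_days`, `birth_weight_g`,
#'   `ga_surgery_weeks`, `ga_surgery_days`, `postnatal_age_days`, `sex`.
#' @export
nec_cohort <- function() {
  path <- system.file("extdata", "nec_cohort.csv", package = "dabquant",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Compare NEC and control groups on both expression statistics
#'
#' Runs the two-sample t-test (pooled by default, plus Welch alongside) on
#' expression per micrometre and on percent DAB-positive area, and computes
#' per-group Pearson correlations of each statistic against gestational age
#' at birth and against postconceptional age at surgery (both in decimal
#' weeks).
#'
#' @param results data frame as from [cohort_results_table()]; requires
#'   columns `group` (values `"NEC"`/`"control"`), `expr_per_um`, `pct_area`,
#'   `ga_birth_weeks`, `ga_birth_days`, `postnatal_age_days`
#' @param variant primary t-test variant, `"pooled"` or `"welch"`
#' @param also_other also report the other variant (default `TRUE`)
#' @return A list of class `cohort_report` with data frames `tests` (one row
#'   per statistic x variant: group means/SDs, t, df, p) and `correlations`
#'   (one row per statistic x predictor x group).
#' @export
compare_groups <- function(results, variant = c("pooled", "welch"),
                           also_other = TRUE) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(results))
  need <- c("group", "expr_per_um", "pct_area", "ga_birth_weeks",
            "ga_birth_days", "postnatal_age_days")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  groups <- unique(results$group)
  if (!all(c("NEC", "control") %in% groups)) {
    stop("insufficient data: both an NEC and a control group are required",
         call. = FALSE)
  }
  nec <- results[results$group == "NEC", ]
  ctl <- results[results$group == "control", ]

  variants <- if (also_other) {
    c(variant, setdiff(c("pooled", "welch"), variant))
  } else variant
  stats_cols <- c(expr_per_um = "expr_per_um", pct_area = "pct_area")
  tests <- do.call(rbind, lapply(names(stats_cols), function(s) {
    do.call(rbind, lapply(variants, function(v) {
      gc <- two_sample_ttest(nec[[s]], ctl[[s]], variant = v)
      data.frame(statistic = s, variant = v,
                 mean_nec = gc$mean_a, sd_nec = gc$sd_a, n_nec = gc$n_a,
                 mean_control = gc$mean_b, sd_control = gc$sd_b,
                 n_control = gc$n_b,
                 t = gc$t, df = gc$df, p = gc$p,
                 stringsAsFactors = FALSE)
    }))
  }))

  ga_birth <- results$ga_birth_weeks + results$ga_birth_days / 7
  ga_surg <- ga_birth + results$postnatal_age_days / 7
  preds <- list(ga_birth_weeks_dec = ga_birth,
                postconceptional_weeks_dec = ga_surg)
  corr_one <- function(s, pname, gname, idx) {
    r <- tryCatch(pearson_correlation(preds[[pname]][idx], results[[s]][idx]),
                  error = function(e) NA_real_)
    data.frame(statistic = s, predictor = pname, group = gname,
               n = sum(idx), r = r, stringsAsFactors = FALSE)
  }
  grid <- expand.grid(s = names(stats_cols), p = names(preds),
                      g = c("NEC", "control"), stringsAsFactors = FALSE)
  correlations <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    corr_one(grid$s[i], grid$p[i], grid$g[i], results$group == grid$g[i])
  }))

  structure(list(tests = tests, correlations = correlations),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\nGroup tests:\n")
  print(x$tests, digits = 6)
  cat("Per-group age correlations:\n")
  print(x$correlations, digits = 6)
  invisible(x)
}
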