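#' Gestational age in completed weeks plus days
#'
#' The neonatal convention: completed weeks and remaining days, with
#' `0 <= days <= 6`. Total age in days is `7 * weeks + days`.
#'
#' @param weeks completed weeks, integer `>= 0`
#' @param days remaining days, integer in `0..6`
#' @return Object of class `gestational_age`.
#' @export
gestational_age <- function(weeks, days = 0L) {
  weeks <- as.integer(weeks); days <- as.integer(days)
  if (is.na(weeks) || is.na(days) || weeks < 0L || days < 0L || days > 6L) {
    stop("invalid age: need weeks >= 0 and 0 <= days <= 6", call. = FALSE)
  }
  structure(list(weeks = weeks, days = days), class = "gestational_age")
}

#' @export
format.gestational_age <- function(x, ...) sprintf("%d+%d", x$weeks, x$days)

#' @export
print.gestational_age <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Total gestational age in days
#' @param ga a [gestational_age()]
#' @return Integer number of days.
#' @export
ga_total_days <- function(ga) {
  stopifnot(inherits(ga, "gestational_age"))
  7L * ga$weeks + ga$days
}

#' Add postnatal days to a gestational age
#'
#' Converts to total days, adds, and converts back to weeks plus days with
#' `0 <= days <= 6`. Used to derive gestational (postconceptional) age at
#' surgery from gestational age at birth and postnatal age at surgery.
#'
#' @param ga a [gestational_age()]
#' @param days integer number of days to add, `>= 0`
#' @return A [gestational_age()].
#' @examples
#' format(ga_add_days(gestational_age(23, 2), 50))  # "30+3"
#' @export
ga_add_days <- function(ga, days) {
  stopifnot(inherits(ga, "gestational_age"))
  days <- as.integer(days)
  if (is.na(days) || days < 0L) {
    stop("invalid age: days to add must be >= 0", call. = FALSE)
  }
  total <- ga_total_days(ga) + days
  gestational_age(total %/% 7L, total %% 7L)
}

#' Gestational age as decimal weeks
#'
#' @param ga a [gestational_age()]
#' @return `weeks + days / 7` as a real number, the encoding used for age
#'   correlations.
#' @export
ga_to_decimal_weeks <- function(ga) {
  stopifnot(inherits(ga, "gestational_age"))
  ga$weeks + ga$days / 7
}
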