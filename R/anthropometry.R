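# Growth-reference z-scores via the LMS (Box-Cox) method: a measurement x
# at a given age and sex is standardized with the reference skewness
# power L, median M, and coefficient of variation S.

#' Interpolate L, M, S at an age
#'
#' Linear interpolation of each of L, M, S between the two bracketing grid
#' ages of the reference table for the given sex; an exact grid age
#' returns that row unchanged.
#'
#' @param table an [lms_table()] (a single measure; if several measures
#'   are present, pass \code{measure}).
#' @param sex "F" or "M".
#' @param age age in years; must lie within the table's span for that sex.
#' @param measure optional measure name to select within a multi-measure
#'   table.
#' @return named numeric vector \code{c(L =, M =, S =)}.
#' @export
#' @examples
#' tab <- lms_table(data.frame(measure = "height", sex = "F",
#'   age_years = c(2, 3), L = 1, M = c(85, 95), S = 0.04))
#' interpolate_lms(tab, "F", 2.5)  # M = 90
interpolate_lms <- function(table, sex, age, measure = NULL) {
  stopifnot(inherits(table, "lms_table"))
  if (!is.null(measure)) table <- table[table$measure == measure, ]
  if (length(unique(table$measure)) > 1) {
    stop_input("LMS table holds several measures; pass 'measure'")
  }
  tab <- table[table$sex == sex, ]
  if (!nrow(tab)) stop_input("unknown sex code '%s'", sex)
  span <- range(tab$age_years)
  if (age < span[1] || age > span[2]) {
    stop_input("age %.3g outside reference span [%.3g, %.3g]",
               age, span[1], span[2])
  }
  c(L = stats::approx(tab$age_years, tab$L, age)$y,
    M = stats::approx(tab$age_years, tab$M, age)$y,
    S = stats::approx(tab$age_years, tab$S, age)$y)
}

#' LMS z-score (Box-Cox standardization)
#'
#' \code{z = ((x/M)^L - 1) / (L S)} for \code{|L| > 1e-8}, and the
#' log-limit \code{z = ln(x/M) / S} otherwise; the two branches agree to
#' below 1e-6 at the switch point.
#'
#' @param x measurement (same units as M); must be positive.
#' @param L,M,S reference parameters (M, S > 0).
#' @return z-score (unitless). Vectorized over all arguments.
#' @seealso [lms_inverse()] for the inverse transform.
#' @export
#' @examples
#' lms_zscore(105, L = 1, M = 100, S = 0.05)  # 1
lms_zscore <- function(x, L, M, S) {
  if (any(x <= 0) || any(M <= 0) || any(S <= 0)) {
    stop_input("lms_zscore needs x > 0, M > 0, S > 0")
  }
  ifelse(abs(L) > 1e-8,
         ((x / M)^L - 1) / (L * S),
         log(x / M) / S)
}

#' Inverse LMS transform: measurement at a given z-score
#' @param z z-score.
#' @inheritParams lms_zscore
#' @return the measurement x with \code{lms_zscore(x, L, M, S) == z}.
#' @export
lms_inverse <- function(z, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) stop_input("lms_inverse needs M > 0, S > 0")
  ifelse(abs(L) > 1e-8,
         M * (1 + L * S * z)^(1 / L),
         M * exp(S * z))
}

#' Mid-upper arm circumference z-scores with a two-table reference
#'
#' Applies the LMS machinery to a MUAC reference. When two tables are
#' supplied (the convention for arm-circumference-for-age references:
#' one for children up to five years, an extended one above), the child's
#' age selects the table; the boundary age belongs to the younger table.
#'
#' @param cohort cohort data.frame with \code{muac_cm}, \code{age_years},
#'   \code{sex}.
#' @param lms_young LMS table covering the younger ages.
#' @param lms_old optional LMS table for ages above \code{boundary_age}.
#' @param boundary_age age (years) at and below which \code{lms_young}
#'   is used. Default 5.
#' @return numeric vector of z-scores, one per participant.
#' @export
muac_zscore <- function(cohort, lms_young, lms_old = NULL,
                        boundary_age = 5) {
  if (!"muac_cm" %in% names(cohort)) stop_input("cohort lacks muac_cm")
  vapply(seq_len(nrow(cohort)), function(i) {
    age <- cohort$age_years[i]
    tab <- if (age <= boundary_age || is.null(lms_old)) lms_young else lms_old
    p <- interpolate_lms(tab, cohort$sex[i], age, measure = "muac")
    lms_zscore(cohort$muac_cm[i], p["L"], p["M"], p["S"])
  }, 0.0)
}

#' Anthropometric z-scores for a cohort
#'
#' Height-for-age, BMI-for-age (BMI computed as weight/height^2 in
#' kg/m^2), and MUAC-for-age z-scores against a supplied LMS reference
#' table set.
#'
#' @param cohort cohort data.frame.
#' @param lms multi-measure [lms_table()] with measures \code{height},
#'   \code{bmi}, \code{muac} (and optionally \code{muac_ext} for ages
#'   above \code{boundary_age}).
#' @param boundary_age MUAC table switch age, years.
#' @return the cohort with added columns \code{bmi}, \code{z_height},
#'   \code{z_bmi}, \code{z_muac}.
#' @export
cohort_zscores <- function(cohort, lms, boundary_age = 5) {
  stopifnot(inherits(lms, "lms_table"))
  cohort$bmi <- cohort$weight_kg / (cohort$height_cm / 100)^2
  one <- function(x, measure, age, sex) {
    p <- interpolate_lms(lms, sex, age, measure = measure)
    lms_zscore(x, p["L"], p["M"], p["S"])
  }
  cohort$z_height <- vapply(seq_len(nrow(cohort)), function(i)
    one(cohort$height_cm[i], "height", cohort$age_years[i], cohort$sex[i]), 0.0)
  cohort$z_bmi <- vapply(seq_len(nrow(cohort)), function(i)
    one(cohort$bmi[i], "bmi", cohort$age_years[i], cohort$sex[i]), 0.0)
  has_ext <- "muac_ext" %in% lms$measure
  cohort$z_muac <- vapply(seq_len(nrow(cohort)), function(i) {
    measure <- if (has_ext && cohort$age_years[i] > boundary_age)
      "muac_ext" else "muac"
    one(cohort$muac_cm[i], measure, cohort$age_years[i], cohort$sex[i])
  }, 0.0)
  cohort
}
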