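#' Body mass index from weight and height
#'
#' Quetelet's equation: weight in kilograms divided by the square of height
#' in metres. Height is taken in centimetres, the unit in which paediatric
#' stature is measured and recorded.
#'
#' @param weight Body weight in kg. Must be strictly positive.
#' @param height Standing height or recumbent length in cm. Must be strictly
#'   positive.
#' @return BMI in kg/m^2 (vectorised over inputs).
#' @examples
#' compute_bmi(51.9, 142.4)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("`weight` must be strictly positive (kg)", call. = FALSE)
  }
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("`height` must be strictly positive (cm)", call. = FALSE)
  }
  weight / (height / 100)^2
}

# Mean Gregorian month length in days; used to express age in real months.
DAYS_PER_MONTH <- 30.4375

#' Chronological age in months and years
#'
#' Age is computed as the day count between birth and examination divided by
#' 30.4375 (the mean Gregorian month). Whole years are the integer truncation
#' of months / 12.
#'
#' @param birth_date,exam_date `Date` objects (or strings coercible via
#'   [as.Date()]). The examination must not precede birth.
#' @return A list with `months` (real-valued) and `years` (integer-truncated).
#' @examples
#' age_in_months("2008-06-15", "2018-03-15")
#' @export
age_in_months <- function(birth_date, exam_date) {
  birth_date <- as.Date(birth_date)
  exam_date <- as.Date(exam_date)
  if (is.na(birth_date) || is.na(exam_date)) {
    stop("dates must be valid ISO-8601 dates", call. = FALSE)
  }
  days <- as.numeric(exam_date - birth_date)
  if (days < 0) {
    stop("`exam_date` precedes `birth_date`", call. = FALSE)
  }
  months <- days / DAYS_PER_MONTH
  list(months = months, years = as.integer(months %/% 12))
}

#' LMS z-score for a measurement against a skewed reference
#'
#' Standard Cole LMS (lambda-mu-sigma) transform used by the WHO and CDC
#' growth references: z = ((x/M)^L - 1) / (L * S), with the Box-Cox power L,
#' median M and coefficient of variation S. As L tends to 0 the transform
#' has the limit z = log(x/M) / S; the log branch is taken for |L| <= 1e-8,
#' where the two branches agree to well below 1e-9.
#'
#' Absolute z-scores above 5 are biologically implausible for BMI-for-age and
#' trigger a warning (no capping is applied).
#'
#' @param bmi Measured BMI in kg/m^2, strictly positive.
#' @param L Box-Cox power (unitless).
#' @param M Reference median, kg/m^2, strictly positive.
#' @param S Reference coefficient of variation, strictly positive.
#' @return z-score (unitless).
#' @export
lms_zscore <- function(bmi, L, M, S) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("`bmi` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(M)) || any(M <= 0)) {
    stop("`M` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(S)) || any(S <= 0)) {
    stop("`S` must be strictly positive", call. = FALSE)
  }
  z <- ifelse(abs(L) > 1e-8,
    ((bmi / M)^L - 1) / (L * S),
    log(bmi / M) / S
  )
  if (any(abs(z) > 5)) {
    warning("|z| > 5: BMI-for-age z-score outside plausibility limits",
      call. = FALSE
    )
  }
  z
}

# Inverse of the LMS transform; the measurement at a given z. Exported both
# for cohort simulation (sampling inside a percentile band) and as the
# round-trip oracle for lms_zscore().
#' Inverse LMS transform
#'
#' Returns the measurement value at z-score `z` for LMS parameters
#' (`L`, `M`, `S`): M * (1 + L*S*z)^(1/L), or M * exp(S*z) for |L| <= 1e-8.
#'
#' @inheritParams lms_zscore
#' @param z z-score (unitless).
#' @return Measurement on the original scale (kg/m^2 for BMI references).
#' @export
lms_inverse <- function(z, L, M, S) {
  if (any(!is.finite(M)) || any(M <= 0) || any(!is.finite(S)) || any(S <= 0)) {
    stop("`M` and `S` must be strictly positive", call. = FALSE)
  }
  ifelse(abs(L) > 1e-8,
    M * (1 + L * S * z)^(1 / L),
    M * exp(S * z)
  )
}

#' Read an LMS growth-reference table
#'
#' Reads a tab-separated reference with columns
#' `sex`, `age_months`, `L`, `M`, `S`. One file may carry both sexes. Ages
#' must be strictly increasing within sex, and M and S strictly positive.
#'
#' The table shipped with the package (`lms_synthetic.tsv`) is a synthetic,
#' smooth, monotone stand-in constructed for testing and examples; it is NOT
#' the WHO reference. Real WHO/CDC LMS tables in the same four-column layout
#' are a drop-in replacement.
#'
#' @param path Path to a TSV file.
#' @return An object of class `lms_table`: a data.frame with the columns
#'   above, validated.
#' @export
read_lms_table <- function(path) {
  if (!file.exists(path)) {
    stop("LMS table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_lms_table(df)
}

#' Construct an LMS table from a data.frame
#'
#' @param df data.frame with columns `sex` ("male"/"female"), `age_months`,
#'   `L`, `M`, `S`.
#' @return A validated `lms_table`.
#' @export
as_lms_table <- function(df) {
  needed <- c("sex", "age_months", "L", "M", "S")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("LMS table lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df <- df[needed]
  if (!all(df$sex %in% c("male", "female"))) {
    stop("LMS table `sex` must be 'male' or 'female'", call. = FALSE)
  }
  if (any(df$M <= 0) || any(df$S <= 0)) {
    stop("LMS table requires M > 0 and S > 0", call. = FALSE)
  }
  for (s in unique(df$sex)) {
    ages <- df$age_months[df$sex == s]
    if (any(diff(ages) <= 0)) {
      stop("LMS table ages must be strictly increasing within sex", call. = FALSE)
    }
  }
  structure(df, class = c("lms_table", "data.frame"))
}

#' @export
print.lms_table <- function(x, ...) {
  for (s in unique(x$sex)) {
    r <- range(x$age_months[x$sex == s])
    cat(sprintf(
      "LMS reference (%s): %d knots, %.1f-%.1f months\n",
      s, sum(x$sex == s), r[1], r[2]
    ))
  }
  invisible(x)
}

#' Interpolate LMS parameters at an age
#'
#' Linear interpolation of L, M and S independently between the bracketing
#' age knots; an exact knot age returns that row unchanged. Ages outside the
#' table range are an error — the reference is never extrapolated.
#'
#' @param table An `lms_table`.
#' @param sex "male" or "female".
#' @param age_months Age in months.
#' @return Named list with `L`, `M`, `S`.
#' @export
lookup_lms <- function(table, sex, age_months) {
  stopifnot(inherits(table, "lms_table"))
  sex <- match.arg(sex, c("male", "female"))
  sub <- table[table$sex == sex, ]
  if (!nrow(sub)) {
    stop("LMS table has no rows for sex '", sex, "'", call. = FALSE)
  }
  if (age_months < min(sub$age_months) || age_months > max(sub$age_months)) {
    stop(sprintf(
      "age %.2f months outside LMS table range [%.1f, %.1f] for %s",
      age_months, min(sub$age_months), max(sub$age_months), sex
    ), call. = FALSE)
  }
  list(
    L = stats::approx(sub$age_months, sub$L, xout = age_months)$y,
    M = stats::approx(sub$age_months, sub$M, xout = age_months)$y,
    S = stats::approx(sub$age_months, sub$S, xout = age_months)$y
  )
}

#' Classify weight status from a BMI-for-age percentile
#'
#' Categories use the percentile cutoffs of the international BMI-for-age
#' reference: underweight below the 5th percentile, normal weight from the
#' 5th up to (not including) the 85th, overweight from the 85th up to (not
#' including) the 95th, and obese at or above the 95th. Intervals are
#' left-closed, right-open.
#'
#' @param percentile BMI-for-age percentile, strictly inside (0, 100).
#' @return One of "underweight", "normal", "overweight", "obese".
#' @export
classify_weight_status <- function(percentile) {
  if (any(!is.finite(percentile)) || any(percentile <= 0) || any(percentile >= 100)) {
    stop("`percentile` must lie strictly inside (0, 100)", call. = FALSE)
  }
  cut_levels <- c("underweight", "normal", "overweight", "obese")
  idx <- findInterval(percentile, c(5, 85, 95)) + 1L
  cut_levels[idx]
}

#' Full BMI-for-age assessment of one child
#'
#' Computes BMI, looks up the LMS reference at the child's age, derives the
#' z-score and percentile (exact standard-normal CDF), and classifies weight
#' status.
#'
#' @param weight,height As in [compute_bmi()].
#' @param sex "male" or "female".
#' @param age_months Age at examination in months.
#' @param lms An `lms_table`.
#' @param measurement_mode "standing_height" or "recumbent_length";
#'   recumbent length is only accepted below 24 months of age.
#' @return Object of class `weight_status`: list with `bmi`, `zscore`,
#'   `percentile`, `category`.
#' @examples
#' lms <- read_lms_table(system.file("extdata", "lms_synthetic.tsv",
#'   package = "peddst"
#' ))
#' assess_weight_status(51.9, 142.4, "male", 116, lms)
#' @export
assess_weight_status <- function(weight, height, sex, age_months, lms,
                                 measurement_mode = c(
                                   "standing_height",
                                   "recumbent_length"
                                 )) {
  measurement_mode <- match.arg(measurement_mode)
  if (measurement_mode == "recumbent_length" && age_months >= 24) {
    stop("recumbent length is only valid below 24 months of age", call. = FALSE)
  }
  bmi <- compute_bmi(weight, height)
  p <- lookup_lms(lms, sex, age_months)
  z <- lms_zscore(bmi, p$L, p$M, p$S)
  pct <- stats::pnorm(z) * 100
  structure(
    list(
      bmi = bmi, zscore = z, percentile = pct,
      category = classify_weight_status(pct)
    ),
    class = "weight_status"
  )
}

#' @export
print.weight_status <- function(x, ...) {
  cat(sprintf(
    "BMI %.2f kg/m2 | z = %+.2f | percentile %.1f | %s\n",
    x$bmi, x$zscore, x$percentile, x$category
  ))
  invisible(x)
}
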