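# Truncated-normal sampling by inverse-CDF (exact, vectorised) and the
# analytic mean of a truncated normal; both are used by the moment-matched
# cohort generator.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  pmin(pmax(x, lower), upper) # guard inverse-CDF edge cases
}

# Mean of a normal truncated to [lower, upper]; tail-stable. For bands far
# above (below) the location the standard phi/Phi ratio underflows, so the
# denominator is evaluated in the appropriate tail and a Mills-ratio
# asymptote is used where even that underflows.
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  num <- stats::dnorm(a) - stats::dnorm(b)
  den <- ifelse(a > 0,
    stats::pnorm(a, lower.tail = FALSE) - stats::pnorm(b, lower.tail = FALSE),
    stats::pnorm(b) - stats::pnorm(a)
  )
  m <- mean + sd * num / den
  bad <- !is.finite(m) | den <= 0
  if (any(bad)) {
    # band entirely in a far tail: mass hugs the nearer bound
    m[bad] <- ifelse(a[bad] > 0,
      lower[bad] + sd / a[bad],
      upper[bad] + sd / b[bad]
    )
  }
  pmin(pmax(m, lower), upper)
}

# Pre-truncation location giving a target post-truncation mean; `lower` and
# `upper` may be per-observation vectors, in which case the average of the
# per-observation truncated means is matched. The average truncated mean is
# increasing in mu, so the root is bracketed by the extreme bounds.
calibrate_mu <- function(target, sd, lower, upper) {
  lower <- rep_len(lower, max(length(lower), length(upper)))
  upper <- rep_len(upper, length(lower))
  f <- function(mu) mean(truncnorm_mean(mu, sd, lower, upper)) - target
  lo <- min(lower) - 10 * sd
  hi <- max(upper) + 10 * sd
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf(
      "target mean %.3f unattainable inside the truncation bands", target
    ), call. = FALSE)
  }
  stats::uniroot(f, interval = c(lo, hi), tol = 1e-8)$root
}

#' Specification of a synthetic overweight/obese cohort
#'
#' Defaults emulate the baseline population of the evaluation trial:
#' 6-12-year-old overweight or obese children with mean age 9.7 y (SEM
#' 0.2), mean BMI 25.1 kg/m^2 (SEM 0.5), 60.7% obese, mean paternal and
#' maternal BMI 28.6 and 27.3 kg/m^2, mean birth weight 3.2 kg, mean
#' physical activity 21.6 min/day and mean maternal pre-pregnancy BMI 24.9
#' kg/m^2. Printed SEMs are converted to SDs with the analysed sample size
#' (SD = SEM * sqrt(n_reference), n_reference = 65). Continuous variables
#' are truncated normals over physiologic ranges with the location
#' calibrated so the post-truncation expectation equals the stated mean.
#' Quantities with no published value (smoking prevalence, activity-category
#' mix, disorder prevalences, parental heights, six-month weight gain) are
#' fixed, documented choices.
#'
#' @param n_children Number of families to generate.
#' @param seed RNG seed (all generation is seeded; no hidden global
#'   randomness).
#' @param age_mean,age_sem,age_range Child age, years.
#' @param bmi_mean,bmi_sem Child BMI, kg/m^2 (band-truncated by weight
#'   status against the LMS reference; upper plausibility bound z = 4).
#' @param obese_fraction Fraction of children drawn obese (the rest are
#'   overweight).
#' @param father_bmi_mean,father_bmi_sem,mother_bmi_mean,mother_bmi_sem
#'   Parental BMI, kg/m^2.
#' @param prepreg_bmi_mean,prepreg_bmi_sem Maternal pre-pregnancy BMI.
#' @param birth_weight_mean,birth_weight_sem Birth weight, kg.
#' @param activity_mean,activity_sem Physical activity, min/day.
#' @param n_reference Sample size behind the printed SEMs.
#' @param female_fraction,smoking_fraction Bernoulli rates.
#' @param activity_probs Probabilities of the light/moderate/vigorous
#'   MET categories.
#' @param disorder_prevalence Named prevalences of the four clinical flags.
#' @param education_probs Probabilities of maternal education < 9, 9-12
#'   and > 12 years.
#' @param exam_date Examination date assigned to every visit.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_children = 200, seed = 1L,
                        age_mean = 9.7, age_sem = 0.2, age_range = c(6, 12.99),
                        bmi_mean = 25.1, bmi_sem = 0.5,
                        obese_fraction = 0.607,
                        father_bmi_mean = 28.6, father_bmi_sem = 0.4,
                        mother_bmi_mean = 27.3, mother_bmi_sem = 0.4,
                        prepreg_bmi_mean = 24.9, prepreg_bmi_sem = 0.4,
                        birth_weight_mean = 3.2, birth_weight_sem = 0.1,
                        activity_mean = 21.6, activity_sem = 2.3,
                        n_reference = 65,
                        female_fraction = 0.5, smoking_fraction = 0.30,
                        activity_probs = c(
                          light = 0.5, moderate = 0.4,
                          vigorous = 0.1
                        ),
                        disorder_prevalence = c(
                          hyperglycaemia = 0.05,
                          insulin_resistance = 0.15,
                          dyslipidaemia = 0.15,
                          hypertension = 0.10
                        ),
                        education_probs = c(
                          less9 = 0.246, mid = 0.328,
                          more12 = 0.426
                        ),
                        exam_date = "2018-05-15") {
  if (n_children <= 0) stop("`n_children` must be positive", call. = FALSE)
  fracs <- c(
    obese_fraction, female_fraction, smoking_fraction,
    activity_probs, disorder_prevalence, education_probs
  )
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("fractions and probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort of families
#'
#' Draws one family per child: weight-status class first (Bernoulli on the
#' obese fraction), then BMI inside that class's percentile band of the LMS
#' reference (truncated normal, location calibrated so the cohort BMI mean
#' matches the spec), height from an age-linked growth line, weight back
#' from BMI, perinatal and parental variables from calibrated truncated
#' normals, and categorical variables from the spec's rates. Fully
#' reproducible under the spec's seed, and every family passes record
#' validation.
#'
#' @param spec A `cohort_spec`.
#' @param lms An `lms_table` used to place the percentile bands; defaults
#'   to the packaged synthetic reference.
#' @return List of families, each a list with `child` (a `child_record`),
#'   `parents` (mother and father `parent_record`s) and `activity_min`.
#' @export
generate_cohort <- function(spec,
                            lms = read_lms_table(system.file("extdata",
                              "lms_synthetic.tsv",
                              package = "peddst"
                            ))) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_children
  sdv <- function(sem) sem * sqrt(spec$n_reference)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  sex <- ifelse(stats::runif(n) < spec$female_fraction, "female", "male")
  age_sd <- sdv(spec$age_sem)
  mu_age <- calibrate_mu(spec$age_mean, age_sd, spec$age_range[1], spec$age_range[2])
  age <- rtruncnorm(n, mu_age, age_sd, spec$age_range[1], spec$age_range[2])
  age_months <- age * 12

  obese <- stats::runif(n) < spec$obese_fraction
  z85 <- stats::qnorm(0.85)
  z95 <- stats::qnorm(0.95)
  params <- lapply(seq_len(n), function(i) lookup_lms(lms, sex[i], age_months[i]))
  lo <- vapply(seq_len(n), function(i) {
    p <- params[[i]]
    lms_inverse(if (obese[i]) z95 else z85, p$L, p$M, p$S)
  }, numeric(1))
  hi <- vapply(seq_len(n), function(i) {
    p <- params[[i]]
    if (obese[i]) lms_inverse(4, p$L, p$M, p$S) else lms_inverse(z95, p$L, p$M, p$S)
  }, numeric(1))
  bmi_sd <- sdv(spec$bmi_sem)
  mu_bmi <- calibrate_mu(spec$bmi_mean, bmi_sd, lo, hi)
  bmi <- rtruncnorm(n, mu_bmi, bmi_sd, lo, hi)

  height <- pmin(pmax(
    142.4 + 5.8 * (age - spec$age_mean) + stats::rnorm(n, 0, 5.9),
    100
  ), 195)
  weight <- bmi * (height / 100)^2
  waist <- pmax(79.9 + 2.5 * (bmi - spec$bmi_mean) + stats::rnorm(n, 0, 4), 45)

  act_sd <- sdv(spec$activity_sem)
  mu_act <- calibrate_mu(spec$activity_mean, act_sd, 0, 180)
  activity_min <- rtruncnorm(n, mu_act, act_sd, 0, 180)
  act_cat <- sample(names(spec$activity_probs), n,
    replace = TRUE,
    prob = spec$activity_probs
  )

  bw_sd <- sdv(spec$birth_weight_sem)
  mu_bw <- calibrate_mu(spec$birth_weight_mean, bw_sd, 1.5, 5.2)
  birth_weight <- rtruncnorm(n, mu_bw, bw_sd, 1.5, 5.2)
  gain <- rtruncnorm(n, 4.0, 1.0, 1.0, 8.0)
  weight_6mo <- birth_weight + gain

  smoking <- stats::runif(n) < spec$smoking_fraction
  pp_sd <- sdv(spec$prepreg_bmi_sem)
  mu_pp <- calibrate_mu(spec$prepreg_bmi_mean, pp_sd, 15, 45)
  prepreg_bmi <- rtruncnorm(n, mu_pp, pp_sd, 15, 45)
  education <- sample(c(8, 11, 16), n, replace = TRUE, prob = spec$education_probs)

  m_sd <- sdv(spec$mother_bmi_sem)
  mu_m <- calibrate_mu(spec$mother_bmi_mean, m_sd, 16, 50)
  mother_bmi <- rtruncnorm(n, mu_m, m_sd, 16, 50)
  mother_height <- stats::rnorm(n, 164, 6)
  f_sd <- sdv(spec$father_bmi_sem)
  mu_f <- calibrate_mu(spec$father_bmi_mean, f_sd, 17, 50)
  father_bmi <- rtruncnorm(n, mu_f, f_sd, 17, 50)
  father_height <- stats::rnorm(n, 177, 7)

  dis_names <- names(spec$disorder_prevalence)
  exam <- as.Date(spec$exam_date)

  lapply(seq_len(n), function(i) {
    birth_date <- exam - round(age_months[i] * DAYS_PER_MONTH)
    disorders <- stats::setNames(
      stats::runif(length(dis_names)) < spec$disorder_prevalence, dis_names
    )
    child <- child_record(
      id = sprintf("syn%04d", i), sex = sex[i],
      birth_date = birth_date, exam_date = exam,
      weight = weight[i], height = height[i],
      activity_category = act_cat[i],
      disorders = disorders, waist = waist[i],
      perinatal = list(
        child_sex = sex[i],
        infant_weight_birth = birth_weight[i],
        infant_weight_6mo = weight_6mo[i],
        maternal_smoking_pregnancy = smoking[i],
        maternal_prepregnancy_bmi = prepreg_bmi[i],
        maternal_education = education[i]
      )
    )
    parents <- list(
      mother = parent_record(
        "mother",
        weight = mother_bmi[i] * (mother_height[i] / 100)^2,
        height = mother_height[i], education_years = education[i]
      ),
      father = parent_record(
        "father",
        weight = father_bmi[i] * (father_height[i] / 100)^2,
        height = father_height[i]
      )
    )
    list(child = child, parents = parents, activity_min = activity_min[i])
  })
}

#' Summary means of a generated cohort
#'
#' @param families Output of [generate_cohort()].
#' @param lms The `lms_table` used for classification.
#' @return Named list of cohort means and fractions, for comparison with
#'   the spec.
#' @export
cohort_summary <- function(families,
                           lms = read_lms_table(system.file("extdata",
                             "lms_synthetic.tsv",
                             package = "peddst"
                           ))) {
  ch <- lapply(families, `[[`, "child")
  bmi <- vapply(ch, function(c) compute_bmi(c$weight, c$height), numeric(1))
  cat_of <- vapply(ch, function(c) {
    assess_weight_status(c$weight, c$height, c$sex, c$age_months, lms)$category
  }, character(1))
  list(
    n = length(families),
    age_years = mean(vapply(ch, function(c) c$age_months / 12, numeric(1))),
    bmi = mean(bmi),
    obese_fraction = mean(cat_of == "obese"),
    overweight_fraction = mean(cat_of == "overweight"),
    father_bmi = mean(vapply(families, function(f) f$parents$father$bmi, numeric(1))),
    mother_bmi = mean(vapply(families, function(f) f$parents$mother$bmi, numeric(1))),
    birth_weight = mean(vapply(
      ch,
      function(c) c$perinatal$infant_weight_birth, numeric(1)
    )),
    activity_min = mean(vapply(families, `[[`, numeric(1), "activity_min")),
    prepreg_bmi = mean(vapply(
      ch,
      function(c) c$perinatal$maternal_prepregnancy_bmi, numeric(1)
    ))
  )
}

#' Construct a family realising a target decision-tree state
#'
#' Stratified generator used to drive every cell of the decision table
#' through the full pipeline: builds a family whose assessment lands on the
#' requested age band, weight status, CORE classification and flags.
#'
#' @param age_band,weight_status,core_risk,any_clinical_disorder,any_obese_parent
#'   Target state coordinates (see [child_state()]).
#' @param lms The `lms_table` the assessment will use.
#' @param exam_date Visit date.
#' @return A family list (`child`, `parents`) for [assess_family()].
#' @export
make_family_for_state <- function(age_band, weight_status, core_risk,
                                  any_clinical_disorder, any_obese_parent,
                                  lms = read_lms_table(system.file("extdata",
                                    "lms_synthetic.tsv",
                                    package = "peddst"
                                  )),
                                  exam_date = "2018-05-15") {
  age_months <- switch(age_band,
    under2 = 12, y2_5 = 48, y6_15 = 116, over15 = 200
  )
  z <- switch(weight_status,
    underweight = stats::qnorm(0.02),
    normal = stats::qnorm(0.50),
    overweight = stats::qnorm(0.90),
    obese = stats::qnorm(0.97)
  )
  sex <- "male"
  p <- lookup_lms(lms, sex, age_months)
  bmi <- lms_inverse(z, p$L, p$M, p$S)
  height <- switch(age_band,
    under2 = 76, y2_5 = 102, y6_15 = 142, over15 = 172
  )
  weight <- bmi * (height / 100)^2
  exam <- as.Date(exam_date)
  perinatal <- if (identical(core_risk, "higher")) {
    list(
      child_sex = sex, infant_weight_birth = 3.2, infant_weight_6mo = 7.9,
      maternal_smoking_pregnancy = TRUE, maternal_prepregnancy_bmi = 31,
      maternal_education = 8
    )
  } else {
    list(
      child_sex = sex, infant_weight_birth = 3.2, infant_weight_6mo = 6.2,
      maternal_smoking_pregnancy = FALSE, maternal_prepregnancy_bmi = 22,
      maternal_education = 16
    )
  }
  child <- child_record(
    id = paste("strat", age_band, weight_status, core_risk,
      as.integer(any_clinical_disorder), as.integer(any_obese_parent),
      sep = "_"
    ),
    sex = sex,
    birth_date = exam - round(age_months * DAYS_PER_MONTH),
    exam_date = exam, weight = weight, height = height,
    measurement_mode = if (age_band == "under2") "recumbent_length" else "standing_height",
    activity_category = "moderate",
    disorders = c(dyslipidaemia = isTRUE(any_clinical_disorder)),
    perinatal = perinatal
  )
  mother_bmi <- if (isTRUE(any_obese_parent)) 33 else 24
  parents <- list(
    mother = parent_record("mother",
      weight = mother_bmi * 1.64^2,
      height = 164, education_years = perinatal$maternal_education
    ),
    father = parent_record("father", weight = 26 * 1.77^2, height = 177)
  )
  list(child = child, parents = parents)
}
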