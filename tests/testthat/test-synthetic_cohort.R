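test_that("change scores and group differences reproduce the printed arithmetic", {
  expect_equal(change_score(16.0, 11.4), -4.6) # sucrose, intervention group
  expect_equal(change_score(13.0, 17.1), 4.1) # fibre, intervention group
  expect_equal(change_score(3.7, 3.7), 0)
  expect_equal(between_group_difference(-0.4, 0.2), -0.6) # BMI change difference
  expect_equal(between_group_difference(0.6, 2.1), -1.5) # waist change difference
  expect_equal(between_group_difference(1.1, 1.1), 0)
})

test_that("the packaged trial summary yields the reported changes", {
  ts <- read_trial_summary()
  ch <- function(v, g) ts$means$change[ts$means$variable == v & ts$means$group == g]
  expect_equal(ch("fibre_g_day", "IG"), 4.1)
  expect_equal(ch("sucrose_g_day", "IG"), -4.6)
  expect_equal(ch("body_weight_kg", "CG"), 1.4)
  expect_equal(ch("waist_cm", "CG"), 2.1)
  expect_equal(ch("bmi_kg_m2", "IG"), -0.4)
  expect_equal(unname(ts$differences["bmi_kg_m2"]), -0.6)
  expect_equal(unname(ts$differences["waist_cm"]), -1.5)
})

test_that("attrition and enrolment planning are exact", {
  a <- attrition(80, 65)
  expect_equal(a$dropped, 15)
  expect_equal(a$rate, 18.75)
  expect_equal(attrition(80, 80), list(dropped = 0, rate = 0))
  expect_error(attrition(60, 65), "exceed")
  expect_equal(plan_enrolment(64, 0.20), 80L)
  expect_error(plan_enrolment(64, 1), "rate")
})

test_that("cohort generation is reproducible under a fixed seed", {
  spec <- cohort_spec(n_children = 25, seed = 11L)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_spec(n_children = 25, seed = 12L))
  expect_false(identical(c1, c3))
})

test_that("cohort moments match the specification within 3 standard errors", {
  spec <- cohort_spec(n_children = 400, seed = 5L)
  fams <- generate_cohort(spec)
  s <- cohort_summary(fams)
  ch <- lapply(fams, `[[`, "child")
  within3se <- function(sample_vals, target) {
    se <- stats::sd(sample_vals) / sqrt(length(sample_vals))
    abs(mean(sample_vals) - target) <= 3 * se
  }
  expect_true(within3se(
    vapply(ch, function(c) c$age_months / 12, numeric(1)),
    spec$age_mean
  ))
  expect_true(within3se(
    vapply(ch, function(c) compute_bmi(c$weight, c$height), numeric(1)),
    spec$bmi_mean
  ))
  expect_true(within3se(
    vapply(fams, function(f) f$parents$father$bmi, numeric(1)),
    spec$father_bmi_mean
  ))
  expect_true(within3se(
    vapply(ch, function(c) c$perinatal$infant_weight_birth, numeric(1)),
    spec$birth_weight_mean
  ))
  expect_true(within3se(
    vapply(fams, `[[`, numeric(1), "activity_min"),
    spec$activity_mean
  ))
  # weight-status mix approximates the spec fraction
  expect_lt(abs(s$obese_fraction - spec$obese_fraction), 0.1)
  expect_equal(s$obese_fraction + s$overweight_fraction, 1)
})

test_that("a degenerate obese fraction of 1 puts every child at or above the 95th", {
  fams <- generate_cohort(cohort_spec(n_children = 40, seed = 3L, obese_fraction = 1))
  lms <- pkg_lms()
  pct <- vapply(fams, function(f) {
    assess_weight_status(
      f$child$weight, f$child$height, f$child$sex,
      f$child$age_months, lms
    )$percentile
  }, numeric(1))
  expect_true(all(pct >= 95))
})

test_that("spec validation rejects impossible parameters", {
  expect_error(cohort_spec(n_children = 0), "positive")
  expect_error(cohort_spec(obese_fraction = 1.2), "\\[0, 1\\]")
})

test_that("every generated family flows through the full pipeline", {
  cfg <- dst_config()
  fams <- generate_cohort(cohort_spec(n_children = 40, seed = 9L))
  for (f in fams) {
    a <- assess_family(f, cfg)
    expect_s3_class(a$report, "report_document")
    expect_true(a$weight_status$category %in% c("overweight", "obese"))
    expect_true(a$outcome$meal_plan %in% c("MP1", "MP2", "MP3", "MP4"))
  }
})

test_that("the stratified generator reaches every non-refer decision cell", {
  cfg <- dst_config()
  states <- enumerate_child_states()
  seen <- character(0)
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    expected <- decide(child_state(
      s$age_band, s$weight_status, s$core_risk,
      s$any_clinical_disorder, s$any_obese_parent
    ))
    fam <- make_family_for_state(
      s$age_band, s$weight_status, s$core_risk,
      s$any_clinical_disorder, s$any_obese_parent
    )
    a <- assess_family(fam, cfg)
    # the realised state must be the targeted one
    expect_equal(unclass(a$state), unname(as.list(s)), ignore_attr = TRUE)
    expect_equal(unclass(a$outcome), unclass(expected), ignore_attr = TRUE)
    if (expected$recommendation != "refer") {
      seen <- c(seen, paste(
        expected$recommendation, expected$meal_plan,
        expected$review_months
      ))
    }
  }
  # all distinct non-refer outcome cells are exercised
  tab <- decision_table()
  nonrefer <- tab$recommendation != "refer"
  expect_setequal(unique(seen), unique(paste(
    tab$recommendation[nonrefer],
    tab$meal_plan[nonrefer], tab$review_months[nonrefer]
  )))
})
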