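test_that("published example cells route correctly", {
  # overweight, no disorder, no obese parent: recommendation 1 + plan 1
  o <- decide(child_state("y6_15", "overweight", "not_applicable", FALSE, FALSE))
  expect_equal(o$recommendation, "R1")
  expect_equal(o$meal_plan, "MP1")
  expect_equal(o$goal, "maintenance")
  expect_equal(o$review_months, 6L)
  # obese 6-15 with disorder and obese parent: family, R4 + hypocaloric MP4
  o <- decide(child_state("y6_15", "obese", "not_applicable", TRUE, TRUE))
  expect_equal(o$recommendation, "R4")
  expect_equal(o$meal_plan, "MP4")
  expect_equal(o$target_population, "family")
  expect_equal(o$goal, "mild_loss")
  expect_equal(o$review_months, 3L)
  # normal weight, lower likelihood: R1, no plan, 12-month review
  o <- decide(child_state("y6_15", "normal", "lower", FALSE, FALSE))
  expect_equal(o$recommendation, "R1")
  expect_equal(o$meal_plan, "none")
  expect_equal(o$review_months, 12L)
})

test_that("obese 2-5-year-olds follow the overweight pathway exactly", {
  for (dis in c(FALSE, TRUE)) {
    for (obp in c(FALSE, TRUE)) {
      ob <- decide(child_state("y2_5", "obese", "not_applicable", dis, obp))
      ow <- decide(child_state("y2_5", "overweight", "not_applicable", dis, obp))
      expect_equal(unclass(ob), unclass(ow))
      expect_equal(ob$goal, "maintenance")
    }
  }
})

test_that("the unstated obese 6-15 cell is filled and flagged as inferred", {
  o <- decide(child_state("y6_15", "obese", "not_applicable", FALSE, FALSE))
  expect_true(o$inferred_cell)
  expect_equal(o$recommendation, "R1")
  expect_equal(o$meal_plan, "MP3")
  expect_equal(o$goal, "mild_loss")
  # all stated cells are not flagged
  expect_false(decide(child_state(
    "y6_15", "obese", "not_applicable",
    TRUE, FALSE
  ))$inferred_cell)
})

test_that("states outside the printed pathways are referred, not errored", {
  refer_states <- list(
    child_state("y6_15", "underweight", "not_applicable", FALSE, FALSE),
    child_state("over15", "obese", "not_applicable", TRUE, TRUE),
    child_state("over15", "normal", "higher", FALSE, FALSE),
    child_state("under2", "obese", "not_applicable", FALSE, FALSE)
  )
  for (s in refer_states) {
    o <- decide(s)
    expect_equal(o$recommendation, "refer")
    expect_equal(o$meal_plan, "none")
    expect_true(is.na(o$review_months))
    expect_length(behaviour_goals(o$recommendation), 0)
  }
})

test_that("state validation enforces the CORE applicability rule", {
  expect_error(
    child_state("y6_15", "normal", "not_applicable", FALSE, FALSE),
    "CORE"
  )
  expect_error(
    child_state("y6_15", "obese", "higher", FALSE, FALSE),
    "only to normal-weight"
  )
  expect_error(
    child_state("y6_15", "obese", "not_applicable", NA, FALSE),
    "TRUE or FALSE"
  )
})

test_that("re-evaluation is memoryless re-classification on the new state", {
  prev <- decide(child_state("y6_15", "obese", "not_applicable", TRUE, FALSE))
  # BMI dropped below the 95th but stayed above the 85th: overweight pathway
  s_ow <- child_state("y6_15", "overweight", "not_applicable", TRUE, FALSE)
  re <- reevaluate(prev, s_ow)
  expect_equal(unclass(re), unclass(decide(s_ow)), ignore_attr = TRUE)
  expect_equal(re$meal_plan, "MP2")
  # BMI dropped below the 85th: back to the normal-weight pathway
  s_nw <- child_state("y6_15", "normal", "lower", FALSE, FALSE)
  re2 <- reevaluate(prev, s_nw)
  expect_equal(re2$review_months, 12L)
  expect_equal(re2$meal_plan, "none")
  # unchanged state reproduces the same outcome
  s_same <- child_state("y6_15", "obese", "not_applicable", TRUE, FALSE)
  expect_equal(unclass(reevaluate(prev, s_same)), unclass(decide(s_same)),
    ignore_attr = TRUE
  )
  # the previous outcome is retained for the trajectory section only
  expect_identical(attr(re, "previous"), prev)
})

test_that("behaviour goals follow the recommendation-level table", {
  base <- c("balanced_diet", "physical_activity", "sleep")
  expect_setequal(behaviour_goals("R1"), base)
  expect_setequal(behaviour_goals("R2"), base)
  expect_length(behaviour_goals("R4"), 5)
  # R3 and R4 share the goal set; they differ only in target population
  expect_setequal(behaviour_goals("R3"), behaviour_goals("R4"))
  o3 <- decide(child_state("y6_15", "overweight", "not_applicable", TRUE, FALSE))
  o4 <- decide(child_state("y6_15", "overweight", "not_applicable", TRUE, TRUE))
  expect_equal(o3$target_population, "child")
  expect_equal(o4$target_population, "family")
})

test_that("age bands partition the age axis at 24, 72 and 192 months", {
  expect_equal(age_band_from_months(c(0, 23.9)), c("under2", "under2"))
  expect_equal(age_band_from_months(24), "y2_5")
  expect_equal(age_band_from_months(71.9), "y2_5")
  expect_equal(age_band_from_months(72), "y6_15")
  expect_equal(age_band_from_months(191.9), "y6_15")
  expect_equal(age_band_from_months(192), "over15")
  expect_error(age_band_from_months(-1), "non-negative")
})

test_that("the enumerated state space is total and structurally sound", {
  states <- enumerate_child_states()
  expect_equal(nrow(states), 80) # 4 bands x (8 normal + 12 other)
  tab <- decision_table()
  expect_equal(nrow(tab), 80)
  expect_false(any(is.na(tab$recommendation)))
  grid_states <- tab$recommendation != "refer" &
    !(tab$weight_status == "normal" & tab$core_risk == "lower")
  # family targeting iff an obese parent, on the 2x2 grid cells
  expect_equal(
    tab$target_population[grid_states] == "family",
    tab$any_obese_parent[grid_states]
  )
  # composition goals iff a clinical disorder, on the 2x2 grid cells
  has_comp <- vapply(
    tab$recommendation[grid_states],
    function(r) "increase_fibre_complex_carb" %in% behaviour_goals(r),
    logical(1)
  )
  expect_equal(unname(has_comp), tab$any_clinical_disorder[grid_states])
  # hypocaloric plans only for obese 6-15-year-olds
  hypo <- tab$meal_plan %in% c("MP3", "MP4")
  expect_equal(hypo, tab$weight_status == "obese" & tab$age_band == "y6_15")
  # meal plan present iff overweight or obese (non-refer rows)
  nonrefer <- tab$recommendation != "refer"
  expect_equal(
    tab$meal_plan[nonrefer] != "none",
    tab$weight_status[nonrefer] %in% c("overweight", "obese")
  )
  # 3-month review only for overweight/obese with a disorder or obese parent
  fast <- !is.na(tab$review_months) & tab$review_months == 3
  expect_equal(
    fast,
    tab$weight_status %in% c("overweight", "obese") &
      (tab$any_clinical_disorder | tab$any_obese_parent) &
      tab$recommendation != "refer"
  )
})
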