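test_that("EER matches direct evaluation of the published equations", {
  # boy 9-18 y band, sedentary
  expect_equal(estimate_eer("male", 10, 40, 1.40, 1.0),
    88.5 - 61.9 * 10 + 1.0 * (26.7 * 40 + 903 * 1.40) + 25,
    tolerance = 1e-9
  )
  expect_equal(estimate_eer("male", 10, 40, 1.40, 1.0), 1826.7, tolerance = 1e-6)
  # girl 9-18 y band, sedentary
  expect_equal(estimate_eer("female", 10, 40, 1.40, 1.0),
    135.3 - 30.8 * 10 + 1.0 * (10.0 * 40 + 934 * 1.40) + 25,
    tolerance = 1e-9
  )
  # 3-8 y band uses the 20 kcal growth constant
  expect_equal(estimate_eer("female", 5, 19, 1.10, 1.16),
    135.3 - 30.8 * 5 + 1.16 * (10.0 * 19 + 934 * 1.10) + 20,
    tolerance = 1e-9
  )
  # infant band: TEE (89 w - 100) plus deposition energy
  expect_equal(estimate_eer("male", 5 / 12, 6, 0.64), 89 * 6 - 100 + 56)
  expect_equal(estimate_eer("female", 2, 12, 0.86), 89 * 12 - 100 + 20)
})

test_that("EER increases with PA, weight and height and refuses adults", {
  base <- estimate_eer("male", 10, 40, 1.40, 1.0)
  expect_gt(estimate_eer("male", 10, 40, 1.40, 1.13), base)
  expect_gt(estimate_eer("male", 10, 44, 1.40, 1.0), base)
  expect_gt(estimate_eer("male", 10, 40, 1.48, 1.0), base)
  expect_error(estimate_eer("male", 19, 70, 1.75, 1.0), "outside the supported bands")
  expect_error(estimate_eer("male", 10, -5, 1.4), "positive")
})

test_that("MET categories map onto bounded IOM PA coefficients", {
  k <- read_eer_constants()
  light <- activity_profile("light", "male", k)
  expect_equal(light$pa_level, "sedentary")
  expect_equal(light$pa_coefficient, 1.00)
  mod_f <- activity_profile("moderate", "female", k)
  expect_equal(mod_f$pa_coefficient, 1.16)
  vig_m <- activity_profile("vigorous", "male", k)
  expect_equal(vig_m$pa_coefficient, 1.26)
  for (cat in c("light", "moderate", "vigorous")) {
    for (sex in c("male", "female")) {
      co <- activity_profile(cat, sex, k)$pa_coefficient
      expect_gte(co, 1.0)
      expect_lte(co, 1.6)
    }
  }
})

test_that("goal application is isocaloric or a floored deficit", {
  expect_equal(apply_goal(1800, "maintenance"), 1800)
  expect_equal(apply_goal(1800, "mild_loss", deficit = 0.15), 1530)
  expect_lt(apply_goal(2000, "mild_loss", deficit = 0.05), 2000)
  expect_error(apply_goal(1800, "mild_loss", deficit = 1.0), "deficit")
  expect_error(apply_goal(1300, "mild_loss", deficit = 0.15), "floor")
  expect_error(apply_goal(-5, "maintenance"), "positive")
})

test_that("macronutrient targets use 4/9/4 Atwater factors inside the AMDRs", {
  m <- macronutrient_targets(1800, c(carb = 50, fat = 30, protein = 20))
  expect_equal(m$grams[m$macro == "carb"], 225)
  expect_equal(m$grams[m$macro == "fat"], 60)
  expect_equal(m$grams[m$macro == "protein"], 90)
  expect_equal(m$pct, c(50, 30, 20))
  # energy conservation
  expect_equal(sum(m$grams * c(4, 9, 4)), 1800, tolerance = 0.5)
  expect_error(
    macronutrient_targets(1800, c(carb = 50, fat = 30, protein = 19)),
    "sums"
  )
  expect_error(
    macronutrient_targets(2000, c(carb = 70, fat = 20, protein = 10)),
    "carb.*AMDR"
  )
})

test_that("energy conservation holds across random admissible splits", {
  set.seed(7)
  for (i in 1:25) {
    carb <- runif(1, 45, 65)
    fat <- runif(1, 25, 35)
    protein <- 100 - carb - fat
    if (protein < 10 || protein > 30) next
    e <- runif(1, 900, 2600)
    m <- macronutrient_targets(e, c(carb = carb, fat = fat, protein = protein))
    expect_equal(sum(m$grams * c(4, 9, 4)), e, tolerance = 0.5)
  }
})

test_that("meal-plan scaling is proportional, rounded, and AMDR-rechecked", {
  plans <- load_meal_plans()
  expect_setequal(names(plans), c("MP1", "MP2", "MP3", "MP4"))
  mp1 <- plans$MP1
  # identity at the reference energy (counts already on the half grid)
  same <- scale_meal_plan(mp1, mp1$reference_energy)
  expect_equal(same$counts, mp1$exchanges)
  expect_length(same$warnings, 0)
  # doubling doubles every count before rounding (halves stay on grid)
  twice <- scale_meal_plan(mp1, 2 * mp1$reference_energy)
  expect_equal(unlist(twice$counts), 2 * unlist(mp1$exchanges))
  # arbitrary factor rounds to the half-exchange grid
  sc <- scale_meal_plan(mp1, 1.125 * mp1$reference_energy)
  expect_equal(
    unlist(sc$counts),
    round(unlist(mp1$exchanges) * 1.125 / 0.5) * 0.5
  )
  expect_error(scale_meal_plan(mp1, -100), "positive")
})

test_that("rounding distortions outside the AMDR are reported as warnings", {
  fatty <- structure(
    list(
      id = "toy", reference_energy = 90, granularity = 0.5,
      exchanges = list(fat = 2)
    ),
    class = "meal_plan_template"
  )
  out <- scale_meal_plan(fatty, 90)
  expect_true(any(grepl("outside AMDR", out$warnings)))
})

test_that("prescription bundles EER, target and macros coherently", {
  p <- prescribe_energy("male", 10, 40, 140,
    goal = "mild_loss",
    deficit = 0.15
  )
  expect_equal(p$target_energy, p$eer * 0.85)
  expect_lt(p$target_energy, p$eer)
  expect_equal(sum(p$macros$pct), 100)
  m <- prescribe_energy("male", 10, 40, 140, goal = "maintenance")
  expect_equal(m$target_energy, m$eer)
})
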