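#' Configuration bundle for the assessment pipeline
#'
#' Collects every tunable the tool exposes: the LMS reference, the CORE
#' score table, the meal-plan templates, the EER constants, the hypocaloric
#' deficit and its floor, the default macronutrient split and the AMDRs.
#'
#' @param lms An `lms_table`; defaults to the packaged synthetic reference
#'   (examples/testing only; supply a real WHO table for clinical use).
#' @param core_table A `core_score_table`; defaults to the packaged
#'   placeholder.
#' @param plans Named list of `meal_plan_template`s; defaults to the
#'   packaged MP1-MP4.
#' @param eer_constants An `eer_constants` object.
#' @param deficit,floor Hypocaloric deficit fraction and kcal/day floor
#'   (see [apply_goal()]).
#' @param split Default macronutrient percentage split.
#' @param amdr AMDR bounds.
#' @return List of class `dst_config`.
#' @export
dst_config <- function(lms = read_lms_table(system.file("extdata",
                         "lms_synthetic.tsv",
                         package = "peddst"
                       )),
                       core_table = read_core_table(default_core_table_path()),
                       plans = load_meal_plans(),
                       eer_constants = read_eer_constants(),
                       deficit = 0.15, floor = 1200,
                       split = c(carb = 52, fat = 30, protein = 18),
                       amdr = default_amdr()) {
  structure(
    list(
      lms = lms, core_table = core_table, plans = plans,
      eer_constants = eer_constants, deficit = deficit, floor = floor,
      split = split, amdr = amdr
    ),
    class = "dst_config"
  )
}

#' Run the full assessment pipeline for one family
#'
#' Assesses the child's weight status against the growth reference, scores
#' the CORE index when the child is normal weight, derives the child state
#' (clinical-disorder flags collapsed by OR, parents categorised obese at
#' BMI > 30), routes it through the decision tree, and — when a meal plan
#' is assigned — computes the energy prescription (EER on measured weight,
#' goal-adjusted target, macronutrient targets) and scales the template.
#' Everything is assembled into the level-5 report.
#'
#' @param family A list with `child` (a `child_record`) and `parents`
#'   (list of `parent_record`s), as returned by [load_records()].
#' @param config A `dst_config`.
#' @return Object of class `dst_assessment`: list with `child`, `parents`,
#'   `weight_status`, `core`, `state`, `outcome`, `prescription`,
#'   `scaled_plan`, `report`.
#' @examples
#' cfg <- dst_config()
#' fam <- list(
#'   child = child_record(
#'     "c1", "male", "2008-06-15", "2018-05-15",
#'     51.9, 142.4,
#'     disorders = c(dyslipidaemia = TRUE)
#'   ),
#'   parents = list(mother = parent_record("mother", 72, 163))
#' )
#' a <- assess_family(fam, cfg)
#' a$outcome
#' @export
assess_family <- function(family, config = dst_config()) {
  stopifnot(inherits(config, "dst_config"))
  child <- family$child
  parents <- family$parents
  stopifnot(inherits(child, "child_record"))

  warn <- character(0)
  ws <- withCallingHandlers(
    assess_weight_status(
      child$weight, child$height, child$sex, child$age_months,
      config$lms, child$measurement_mode
    ),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  core <- NULL
  core_risk <- "not_applicable"
  if (ws$category == "normal") {
    perinatal <- child$perinatal
    if (is.null(perinatal)) {
      perinatal <- list(child_sex = child$sex)
      warn <- c(warn, "no perinatal record: CORE scored with all components missing")
    }
    core <- score_core(perinatal, config$core_table, weight_status = ws$category)
    core_risk <- if (core$classification == "higher_likelihood") "higher" else "lower"
  }

  any_dis <- any(child$disorders)
  any_obp <- length(parents) > 0 && any(vapply(parents, function(p) p$obese, logical(1)))
  if (!length(parents)) {
    warn <- c(warn, "no parent records: obese-parent flag assumed FALSE")
  }

  state <- child_state(
    age_band_from_months(child$age_months), ws$category, core_risk,
    any_dis, any_obp
  )
  outcome <- decide(state)
  attr(outcome, "child_id") <- child$id

  prescription <- NULL
  scaled <- NULL
  if (outcome$meal_plan != "none") {
    act <- activity_profile(child$activity_category, child$sex, config$eer_constants)
    prescription <- prescribe_energy(
      sex = child$sex, age_years = child$age_months / 12,
      weight = child$weight, height = child$height, activity = act,
      goal = outcome$goal, split = config$split,
      deficit = config$deficit, floor = config$floor, amdr = config$amdr,
      constants = config$eer_constants
    )
    scaled <- scale_meal_plan(
      config$plans[[outcome$meal_plan]],
      prescription$target_energy, config$amdr
    )
  }

  if (!is.null(core) && core$n_missing > 0) {
    warn <- c(warn, sprintf("CORE scored with %d missing component(s)", core$n_missing))
  }
  if (outcome$inferred_cell) {
    warn <- c(warn, "decision cell not stated in the published pathway (inferred by symmetry)")
  }

  report <- build_report(child, parents, outcome,
    prescription = prescription,
    weight_status = ws, core = core, scaled_plan = scaled,
    warnings = warn
  )
  structure(
    list(
      child = child, parents = parents, weight_status = ws, core = core,
      state = state, outcome = outcome, prescription = prescription,
      scaled_plan = scaled, report = report
    ),
    class = "dst_assessment"
  )
}

#' @export
print.dst_assessment <- function(x, ...) {
  print(x$weight_status)
  print(x$outcome)
  invisible(x)
}
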