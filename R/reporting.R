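REPORT_SCHEMA_VERSION <- "1.0"

#' Build the clinician-facing report document
#'
#' Assembles the assessment report: (a) current weight status and the
#' weight-management goal, (b) future-obesity likelihood (normal-weight
#' children only), (c) total energy requirement, (d) macronutrient needs,
#' (e) the assigned meal plan, and (f) the recommendation level with its
#' behavioural-change goals, plus a provenance block (inputs, config
#' versions, inferred-cell flag, warnings). Items (c)-(e) are present
#' exactly when a meal plan was assigned; item (b) exactly when the child
#' is currently normal weight.
#'
#' @param child A `child_record`.
#' @param parents List of `parent_record`s (possibly empty).
#' @param outcome The `decision_outcome` for this child. If it carries a
#'   `child_id` attribute it must match `child$id`.
#' @param prescription The `energy_prescription`, or `NULL` when no meal
#'   plan applies.
#' @param weight_status The `weight_status` object for this child.
#' @param core Optional `core_result` (normal-weight children).
#' @param scaled_plan Optional `scaled_meal_plan`.
#' @param warnings Character vector of warnings accumulated upstream.
#' @return Object of class `report_document`.
#' @export
build_report <- function(child, parents, outcome, prescription = NULL,
                         weight_status, core = NULL, scaled_plan = NULL,
                         warnings = character(0)) {
  stopifnot(
    inherits(child, "child_record"),
    inherits(outcome, "decision_outcome"),
    inherits(weight_status, "weight_status")
  )
  oid <- attr(outcome, "child_id")
  if (!is.null(oid) && !identical(oid, child$id)) {
    stop("decision outcome belongs to child '", oid, "', not '", child$id,
      "' (integrity error)",
      call. = FALSE
    )
  }
  has_plan <- outcome$meal_plan != "none"
  if (has_plan && (is.null(prescription) || is.null(scaled_plan))) {
    stop("a meal plan was assigned but no energy prescription/scaled plan ",
      "was supplied",
      call. = FALSE
    )
  }
  if (!has_plan && (!is.null(prescription) || !is.null(scaled_plan))) {
    stop("no meal plan assigned: energy items do not apply", call. = FALSE)
  }
  is_normal <- weight_status$category == "normal"
  if (is_normal && is.null(core)) {
    stop("normal-weight children require a CORE result for report item (b)",
      call. = FALSE
    )
  }
  if (!is_normal && !is.null(core)) {
    stop("future-obesity likelihood applies only to normal-weight children",
      call. = FALSE
    )
  }

  items <- list(
    a_weight_status = list(
      bmi = weight_status$bmi,
      zscore = weight_status$zscore,
      percentile = weight_status$percentile,
      category = weight_status$category,
      goal = outcome$goal
    )
  )
  if (is_normal) {
    items$b_future_obesity_likelihood <- list(
      core_score = core$score,
      classification = core$classification,
      n_missing_components = core$n_missing
    )
  }
  if (has_plan) {
    items$c_energy_requirement <- list(
      eer_kcal_day = prescription$eer,
      target_kcal_day = prescription$target_energy,
      goal = prescription$goal
    )
    items$d_macronutrients <- prescription$macros
    items$e_meal_plan <- list(
      plan_id = scaled_plan$plan_id,
      daily_exchanges = scaled_plan$counts,
      delivered_kcal_day = scaled_plan$energy_kcal
    )
  }
  items$f_recommendations <- list(
    recommendation = outcome$recommendation,
    target_population = outcome$target_population,
    behaviour_goals = behaviour_goals(outcome$recommendation),
    review_months = outcome$review_months
  )

  structure(
    list(
      schema_version = REPORT_SCHEMA_VERSION,
      child_id = child$id,
      exam_date = child$exam_date,
      items = items,
      provenance = list(
        inputs = list(
          sex = child$sex, age_months = child$age_months,
          weight_kg = child$weight, height_cm = child$height,
          measurement_mode = child$measurement_mode,
          activity_category = child$activity_category,
          disorders = as.list(child$disorders),
          n_parents = length(parents),
          parent_bmi = lapply(parents, function(p) p$bmi),
          eer_uses_measured_weight = TRUE
        ),
        inferred_cell = outcome$inferred_cell,
        warnings = c(
          warnings,
          if (!is.null(scaled_plan)) scaled_plan$warnings
        )
      )
    ),
    class = "report_document"
  )
}

#' Serialise a report
#'
#' JSON output is schema-versioned, deterministic and round-trips
#' losslessly through [parse_report()]; Markdown is a human-readable
#' rendering of the same content with one section per populated item.
#'
#' @param report A `report_document`.
#' @param format "json" or "markdown".
#' @return A character scalar (the document).
#' @export
render <- function(report, format = c("json", "markdown")) {
  stopifnot(inherits(report, "report_document"))
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      unclass(report),
      auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null"
    )))
  }
  md <- c(
    sprintf("# Assessment report: child %s", report$child_id),
    sprintf("Examination date: %s", report$exam_date),
    ""
  )
  it <- report$items
  a <- it$a_weight_status
  md <- c(
    md, "## (a) Weight status",
    sprintf(
      "BMI %.2f kg/m2, z-score %+.2f, percentile %.1f: **%s**; goal: %s.",
      a$bmi, a$zscore, a$percentile, a$category, a$goal
    ), ""
  )
  if (!is.null(it$b_future_obesity_likelihood)) {
    b <- it$b_future_obesity_likelihood
    md <- c(
      md, "## (b) Future obesity likelihood",
      sprintf(
        "CORE score %d: %s (%d missing component(s)).",
        b$core_score, b$classification, b$n_missing_components
      ), ""
    )
  }
  if (!is.null(it$c_energy_requirement)) {
    cc <- it$c_energy_requirement
    md <- c(
      md, "## (c) Energy requirement",
      sprintf(
        "EER %.0f kcal/day; %s target %.0f kcal/day.",
        cc$eer_kcal_day, cc$goal, cc$target_kcal_day
      ), ""
    )
  }
  if (!is.null(it$d_macronutrients)) {
    d <- it$d_macronutrients
    md <- c(md, "## (d) Macronutrient needs", vapply(
      seq_len(nrow(d)),
      function(i) {
        sprintf(
          "- %s: %.1f%% of energy, %.1f g/day", d$macro[i], d$pct[i],
          d$grams[i]
        )
      }, character(1)
    ), "")
  }
  if (!is.null(it$e_meal_plan)) {
    e <- it$e_meal_plan
    md <- c(
      md, "## (e) Meal plan",
      sprintf(
        "%s (%.0f kcal/day as delivered); daily exchanges: %s.",
        e$plan_id, e$delivered_kcal_day,
        paste(sprintf(
          "%s %.1f", names(e$daily_exchanges),
          unlist(e$daily_exchanges)
        ), collapse = ", ")
      ), ""
    )
  }
  f <- it$f_recommendations
  md <- c(
    md, "## (f) Recommendations",
    sprintf(
      "%s (target: %s); review in %s months.", f$recommendation,
      f$target_population,
      ifelse(is.na(f$review_months), "-", f$review_months)
    ),
    paste("Behavioural goals:", paste(unlist(f$behaviour_goals),
      collapse = ", "
    )), ""
  )
  w <- unlist(report$provenance$warnings)
  if (length(w)) {
    md <- c(md, "## Warnings", paste("-", w), "")
  }
  paste(md, collapse = "\n")
}

#' Parse a JSON report back into a report document
#'
#' @param json JSON string produced by [render()].
#' @return A `report_document`.
#' @export
parse_report <- function(json) {
  x <- jsonlite::fromJSON(json,
    simplifyVector = TRUE,
    simplifyDataFrame = TRUE
  )
  structure(x, class = "report_document")
}

#' @export
print.report_document <- function(x, ...) {
  cat(render(x, "markdown"))
  invisible(x)
}
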