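AGE_BANDS <- c("under2", "y2_5", "y6_15", "over15")
WEIGHT_CATEGORIES <- c("underweight", "normal", "overweight", "obese")
CORE_LEVELS <- c("higher", "lower", "not_applicable")

#' Age band for the decision pathways
#'
#' @param age_months Age in months.
#' @return "under2" (< 24 months), "y2_5" (2-5 years), "y6_15"
#'   (6-15 years) or "over15" (16 years and older).
#' @export
age_band_from_months <- function(age_months) {
  if (any(!is.finite(age_months)) || any(age_months < 0)) {
    stop("`age_months` must be non-negative", call. = FALSE)
  }
  bands <- AGE_BANDS[findInterval(age_months, c(24, 72, 192)) + 1L]
  bands
}

#' Child state entering the decision tree
#'
#' The five coordinates the pathways route on: age band, current weight
#' status, future-obesity likelihood (CORE classification, applicable only
#' to normal-weight children), presence of at least one clinical disorder
#' (hyperglycaemia, insulin resistance, dyslipidaemia or hypertension,
#' collapsed by OR), and presence of at least one obese parent
#' (parental BMI > 30 kg/m^2).
#'
#' @param age_band One of "under2", "y2_5", "y6_15", "over15".
#' @param weight_status One of "underweight", "normal", "overweight",
#'   "obese".
#' @param core_risk "higher", "lower", or "not_applicable". Must be
#'   "not_applicable" exactly when `weight_status` is not "normal".
#' @param any_clinical_disorder Logical.
#' @param any_obese_parent Logical.
#' @return Object of class `child_state`.
#' @export
child_state <- function(age_band, weight_status, core_risk,
                        any_clinical_disorder, any_obese_parent) {
  age_band <- match.arg(age_band, AGE_BANDS)
  weight_status <- match.arg(weight_status, WEIGHT_CATEGORIES)
  core_risk <- match.arg(core_risk, CORE_LEVELS)
  if (!is.logical(any_clinical_disorder) || is.na(any_clinical_disorder) ||
    !is.logical(any_obese_parent) || is.na(any_obese_parent)) {
    stop("disorder and obese-parent flags must be TRUE or FALSE", call. = FALSE)
  }
  if (weight_status == "normal" && core_risk == "not_applicable") {
    stop("normal-weight children require a CORE classification", call. = FALSE)
  }
  if (weight_status != "normal" && core_risk != "not_applicable") {
    stop("CORE risk applies only to normal-weight children", call. = FALSE)
  }
  structure(
    list(
      age_band = age_band, weight_status = weight_status,
      core_risk = core_risk,
      any_clinical_disorder = any_clinical_disorder,
      any_obese_parent = any_obese_parent
    ),
    class = "child_state"
  )
}

new_outcome <- function(recommendation, meal_plan, goal, review_months,
                        inferred_cell = FALSE) {
  structure(
    list(
      recommendation = recommendation,
      meal_plan = meal_plan,
      target_population = if (recommendation %in% c("R2", "R4")) "family" else "child",
      goal = goal,
      review_months = review_months,
      inferred_cell = inferred_cell
    ),
    class = "decision_outcome"
  )
}

# Shared 2x2 recommendation grid on (any disorder, any obese parent):
# (F,F) -> R1, (F,T) -> R2, (T,F) -> R3, (T,T) -> R4.
recommendation_grid <- function(dis, obp) {
  if (!dis && !obp) "R1" else if (!dis && obp) "R2" else if (dis && !obp) "R3" else "R4"
}

#' Decide the management pathway for a child state
#'
#' Implements the full five-step decision tree:
#' \itemize{
#'   \item normal weight, lower likelihood: recommendation 1, no meal plan;
#'   \item normal weight, higher likelihood: recommendations 1-4 on the
#'     disorder x obese-parent grid, no meal plan; re-evaluation every 6
#'     months with a disorder or obese parent, else every 12;
#'   \item overweight (and obese 2-5-year-olds, who follow the same
#'     pathway): recommendations 1-4 with isocaloric meal plan 1 (no
#'     disorder) or 2 (disorder), weight-maintenance goal; re-evaluation
#'     every 3 months with a disorder or obese parent, else every 6;
#'   \item obese 6-15-year-olds: mild weight loss with hypocaloric meal
#'     plan 3 (no disorder) or 4 (disorder); the no-disorder /
#'     non-obese-parent cell is not stated in the published pathway and is
#'     filled by symmetry (recommendation 1 + plan 3), flagged
#'     `inferred_cell`;
#'   \item underweight, 16 years and older, or obese under 2 years:
#'     outside every printed pathway, returned as an explicit "refer"
#'     outcome (no plan, no interval).
#' }
#'
#' @param state A `child_state`.
#' @return Object of class `decision_outcome` with fields
#'   `recommendation` ("R1".."R4" or "refer"), `meal_plan` ("none",
#'   "MP1".."MP4"), `target_population` ("child"/"family"; family exactly
#'   for R2 and R4), `goal` ("none", "maintenance", "mild_loss"),
#'   `review_months` (3, 6, 12, or NA for refer), `inferred_cell`.
#' @examples
#' decide(child_state("y6_15", "obese", "not_applicable", TRUE, TRUE))
#' @export
decide <- function(state) {
  stopifnot(inherits(state, "child_state"))
  dis <- state$any_clinical_disorder
  obp <- state$any_obese_parent
  refer <- new_outcome("refer", "none", "none", NA_integer_)

  if (state$weight_status == "underweight" || state$age_band == "over15") {
    return(refer)
  }

  if (state$weight_status == "normal") {
    rec <- if (state$core_risk == "lower") "R1" else recommendation_grid(dis, obp)
    review <- if (dis || obp) 6L else 12L
    return(new_outcome(rec, "none", "none", review))
  }

  step4 <- function() {
    rec <- recommendation_grid(dis, obp)
    plan <- if (dis) "MP2" else "MP1"
    review <- if (dis || obp) 3L else 6L
    new_outcome(rec, plan, "maintenance", review)
  }

  if (state$weight_status == "overweight") {
    return(step4())
  }

  # obese
  if (state$age_band == "under2") {
    return(refer)
  }
  if (state$age_band == "y2_5") {
    return(step4())
  }
  # obese 6-15 y: mild weight loss, hypocaloric plans
  rec <- recommendation_grid(dis, obp)
  plan <- if (dis) "MP4" else "MP3"
  review <- if (dis || obp) 3L else 6L
  new_outcome(rec, plan, "mild_loss", review, inferred_cell = (!dis && !obp))
}

#' Re-evaluate a child at follow-up
#'
#' Re-evaluation routes purely on the child's new state: every published
#' transition sentence dispatches on the new BMI percentile alone, so the
#' transition is memoryless and the outcome equals `decide(new_state)`.
#' The previous outcome is retained in the result (attribute `previous`)
#' only for the report's trajectory section.
#'
#' @param previous The `decision_outcome` of the prior visit.
#' @param new_state The `child_state` observed at re-evaluation.
#' @return A `decision_outcome` with attribute `previous`.
#' @export
reevaluate <- function(previous, new_state) {
  stopifnot(inherits(previous, "decision_outcome"))
  out <- decide(new_state)
  attr(out, "previous") <- previous
  out
}

#' Behavioural change goals attached to a recommendation level
#'
#' All four recommendation levels carry the base goals (keep a balanced
#' diet, increase physical activity, improve sleep habits); levels 3 and 4
#' add the dietary-composition goals (increase fibre-rich and
#' complex-carbohydrate foods; reduce foods rich in simple sugars, total
#' and saturated fat, cholesterol and sodium). Levels 1 and 3 address the
#' child, levels 2 and 4 the whole family.
#'
#' @param recommendation "R1".."R4" or "refer".
#' @return Character vector of goal tags (empty for "refer").
#' @export
behaviour_goals <- function(recommendation) {
  if (identical(recommendation, "refer")) {
    return(character(0))
  }
  recommendation <- match.arg(recommendation, c("R1", "R2", "R3", "R4"))
  base <- c("balanced_diet", "physical_activity", "sleep")
  if (recommendation %in% c("R3", "R4")) {
    c(base, "increase_fibre_complex_carb", "reduce_sugar_satfat_chol_sodium")
  } else {
    base
  }
}

#' Enumerate every valid child state
#'
#' The finite state space of the decision tree: 4 age bands x 4 weight
#' statuses x CORE levels x disorder flag x obese-parent flag, restricted
#' to valid combinations (CORE classification present exactly for
#' normal-weight children). 80 states in total.
#'
#' @return data.frame with one row per valid state.
#' @export
enumerate_child_states <- function() {
  grid <- expand.grid(
    age_band = AGE_BANDS,
    weight_status = WEIGHT_CATEGORIES,
    core_risk = CORE_LEVELS,
    any_clinical_disorder = c(FALSE, TRUE),
    any_obese_parent = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  valid <- (grid$weight_status == "normal" & grid$core_risk != "not_applicable") |
    (grid$weight_status != "normal" & grid$core_risk == "not_applicable")
  grid[valid, , drop = FALSE]
}

#' The fully enumerated decision table
#'
#' Applies [decide()] to every valid child state and returns the complete
#' state -> outcome mapping as one data.frame.
#'
#' @return data.frame with the state columns plus `recommendation`,
#'   `meal_plan`, `target_population`, `goal`, `review_months`,
#'   `inferred_cell`.
#' @export
decision_table <- function() {
  states <- enumerate_child_states()
  out <- lapply(seq_len(nrow(states)), function(i) {
    s <- states[i, ]
    o <- decide(child_state(
      s$age_band, s$weight_status, s$core_risk,
      s$any_clinical_disorder, s$any_obese_parent
    ))
    data.frame(
      recommendation = o$recommendation, meal_plan = o$meal_plan,
      target_population = o$target_population, goal = o$goal,
      review_months = o$review_months, inferred_cell = o$inferred_cell
    )
  })
  res <- cbind(states, do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat(sprintf(
    "%s | plan %s | target %s | goal %s | review %s months%s\n",
    x$recommendation, x$meal_plan, x$target_population, x$goal,
    ifelse(is.na(x$review_months), "-", x$review_months),
    if (isTRUE(x$inferred_cell)) " [inferred cell]" else ""
  ))
  invisible(x)
}

#' @export
print.child_state <- function(x, ...) {
  cat(sprintf(
    "child state: %s, %s, CORE %s, disorder=%s, obese parent=%s\n",
    x$age_band, x$weight_status, x$core_risk,
    x$any_clinical_disorder, x$any_obese_parent
  ))
  invisible(x)
}
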