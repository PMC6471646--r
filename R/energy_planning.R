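# Atwater general factors, kcal per gram.
ATWATER <- c(carb = 4, fat = 9, protein = 4)

#' Read the EER coefficient file
#'
#' Estimated-energy-requirement (EER) equations follow the Institute of
#' Medicine Dietary Reference Intakes for infants, children and adolescents.
#' The coefficient sets (age-band intercepts, age/weight/height coefficients,
#' growth-energy constants and physical-activity coefficients) live in a
#' versioned YAML constants file so they can be audited and replaced without
#' touching code. Heights enter the equations in metres.
#'
#' @param path YAML constants file; defaults to the packaged
#'   `eer_constants.yaml`.
#' @return Parsed constants list (class `eer_constants`).
#' @export
read_eer_constants <- function(path = system.file("extdata", "eer_constants.yaml",
                                 package = "peddst"
                               )) {
  if (!file.exists(path)) {
    stop("EER constants file not found: ", path, call. = FALSE)
  }
  x <- yaml::read_yaml(path)
  stopifnot(
    !is.null(x$infant_tee), !is.null(x$infant_bands),
    !is.null(x$child_bands), !is.null(x$pa_coefficients)
  )
  structure(x, class = "eer_constants")
}

#' Physical-activity profile from a MET-based category
#'
#' Clinicians categorise a child's physical activity by intensity in
#' metabolic equivalents: light (< 4 METs), moderate (4-7 METs) or vigorous
#' (> 7 METs). The IOM equations instead use physical-activity (PA) levels
#' (sedentary, low active, active, very active) with sex-specific
#' coefficients. The bridge between the two taxonomies is configuration:
#' the default maps light to sedentary, moderate to low active and vigorous
#' to active.
#'
#' @param category "light", "moderate" or "vigorous".
#' @param sex "male" or "female".
#' @param constants An `eer_constants` object.
#' @return Object of class `activity_profile`: list with `category`,
#'   `pa_level`, `pa_coefficient`.
#' @export
activity_profile <- function(category, sex,
                             constants = read_eer_constants()) {
  category <- match.arg(category, c("light", "moderate", "vigorous"))
  sex <- match.arg(sex, c("male", "female"))
  level <- constants$met_category_map[[category]]
  coef <- constants$pa_coefficients[[sex]][[level]]
  if (is.null(coef) || coef < 1.0 || coef > 1.6) {
    stop("PA coefficient for ", sex, "/", level,
      " missing or outside [1.0, 1.6]",
      call. = FALSE
    )
  }
  structure(
    list(category = category, pa_level = level, pa_coefficient = coef),
    class = "activity_profile"
  )
}

#' Estimated energy requirement (IOM equations)
#'
#' Dispatches on age band:
#' \itemize{
#'   \item 0-35 months: total energy expenditure `89*weight - 100` plus an
#'     age-specific growth-energy constant (sex-independent, PA not used);
#'   \item 3-8 years and 9-18 years: sex-specific linear equations in age,
#'     weight and height with the PA coefficient multiplying the
#'     weight/height term, plus a band-specific growth-energy constant.
#' }
#' Ages of 19 years or more are an explicit unsupported-band error; the
#' equations are never extrapolated.
#'
#' @param sex "male" or "female".
#' @param age_years Age in years (real-valued).
#' @param weight Weight in kg, strictly positive.
#' @param height_m Height in metres, strictly positive.
#' @param pa_coefficient Physical-activity coefficient (from
#'   [activity_profile()]), default 1.0 (sedentary).
#' @param constants An `eer_constants` object.
#' @return EER in kcal/day.
#' @examples
#' estimate_eer("male", 10, 40, 1.40, 1.0)
#' @export
estimate_eer <- function(sex, age_years, weight, height_m,
                         pa_coefficient = 1.0,
                         constants = read_eer_constants()) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.finite(weight) || weight <= 0 || !is.finite(height_m) || height_m <= 0) {
    stop("`weight` and `height_m` must be strictly positive", call. = FALSE)
  }
  if (!is.finite(age_years) || age_years < 0) {
    stop("`age_years` must be non-negative", call. = FALSE)
  }
  if (age_years * 12 < 36) {
    months <- age_years * 12
    tee <- constants$infant_tee$weight_coef * weight +
      constants$infant_tee$intercept
    growth <- NA_real_
    for (b in constants$infant_bands) {
      if (months <= b$max_months) {
        growth <- b$growth_kcal
        break
      }
    }
    return(tee + growth)
  }
  if (age_years >= 19) {
    stop("age ", age_years, " y outside the supported bands ",
      "(0-35 months, 3-8 y, 9-18 y)",
      call. = FALSE
    )
  }
  band <- NULL
  for (b in constants$child_bands[[sex]]) {
    if (age_years >= b$min_years && age_years < b$max_years) {
      band <- b
      break
    }
  }
  if (is.null(band)) {
    stop("no EER band covers age ", age_years, " y for ", sex, call. = FALSE)
  }
  band$intercept + band$age_coef * age_years +
    pa_coefficient * (band$weight_coef * weight + band$height_coef * height_m) +
    band$growth_kcal
}

#' Apply the weight-management goal to an energy requirement
#'
#' Weight maintenance prescribes an isocaloric target (the EER unchanged);
#' mild weight loss prescribes a hypocaloric target, the EER reduced by a
#' configured fractional deficit (default 15%). A target below the safety
#' floor (default 1200 kcal/day for 6-15-year-olds) or non-positive is a
#' configuration error, never silently clamped.
#'
#' @param eer EER in kcal/day, strictly positive.
#' @param goal "maintenance" or "mild_loss".
#' @param deficit Fraction of EER removed under `mild_loss`, in (0, 1).
#' @param floor Minimum admissible target in kcal/day.
#' @return Target energy in kcal/day.
#' @export
apply_goal <- function(eer, goal = c("maintenance", "mild_loss"),
                       deficit = 0.15, floor = 1200) {
  goal <- match.arg(goal)
  if (!is.finite(eer) || eer <= 0) {
    stop("`eer` must be strictly positive", call. = FALSE)
  }
  if (goal == "maintenance") {
    return(eer)
  }
  if (!is.finite(deficit) || deficit <= 0 || deficit >= 1) {
    stop("`deficit` must lie in (0, 1)", call. = FALSE)
  }
  target <- eer * (1 - deficit)
  if (target < floor) {
    stop(sprintf(
      "hypocaloric target %.0f kcal/day below the configured floor %.0f",
      target, floor
    ), call. = FALSE)
  }
  target
}

#' Default acceptable macronutrient distribution ranges
#'
#' IOM AMDRs for 4-18-year-olds, as percent of energy: carbohydrate 45-65,
#' fat 25-35, protein 10-30.
#'
#' @return Named list of `c(min, max)` percent bounds.
#' @export
default_amdr <- function() {
  list(
    carb = c(45, 65),
    fat = c(25, 35),
    protein = c(10, 30)
  )
}

#' Macronutrient targets for an energy prescription
#'
#' Distributes the target energy over carbohydrate, fat and protein using a
#' percentage split, validates the split against the AMDRs, and converts to
#' grams per day with the 4/9/4 Atwater factors.
#'
#' @param target_energy Target energy, kcal/day, strictly positive.
#' @param split Named numeric vector or list with `carb`, `fat`, `protein`
#'   percentages summing to 100 (tolerance 0.01).
#' @param amdr AMDR bounds as from [default_amdr()].
#' @return data.frame with columns `macro`, `pct`, `grams`, `kcal`.
#' @examples
#' macronutrient_targets(1800, c(carb = 50, fat = 30, protein = 20))
#' @export
macronutrient_targets <- function(target_energy, split, amdr = default_amdr()) {
  if (!is.finite(target_energy) || target_energy <= 0) {
    stop("`target_energy` must be strictly positive", call. = FALSE)
  }
  split <- unlist(split)[c("carb", "fat", "protein")]
  if (any(is.na(split))) {
    stop("`split` must name carb, fat and protein percentages", call. = FALSE)
  }
  if (abs(sum(split) - 100) > 0.01) {
    stop(sprintf("macronutrient split sums to %.2f%%, not 100%%", sum(split)),
      call. = FALSE
    )
  }
  for (m in names(split)) {
    b <- amdr[[m]]
    if (split[[m]] < b[1] || split[[m]] > b[2]) {
      stop(sprintf(
        "%s at %.1f%% of energy outside the AMDR [%g%%, %g%%]",
        m, split[[m]], b[1], b[2]
      ), call. = FALSE)
    }
  }
  kcal <- target_energy * split / 100
  data.frame(
    macro = names(split),
    pct = unname(split),
    grams = unname(kcal / ATWATER[names(split)]),
    kcal = unname(kcal),
    row.names = NULL
  )
}

#' Assemble a full energy prescription
#'
#' Convenience wrapper: EER, goal-adjusted target, and macronutrient
#' targets in one object. Height is taken in cm at this boundary and
#' converted to metres for the equations.
#'
#' @inheritParams estimate_eer
#' @param height Height in cm.
#' @param activity An `activity_profile` (or `NULL` for sedentary).
#' @param goal "maintenance" or "mild_loss".
#' @param split Macronutrient percentage split (see
#'   [macronutrient_targets()]).
#' @param deficit,floor Passed to [apply_goal()].
#' @param amdr Passed to [macronutrient_targets()].
#' @return Object of class `energy_prescription`.
#' @export
prescribe_energy <- function(sex, age_years, weight, height, activity = NULL,
                             goal = c("maintenance", "mild_loss"),
                             split = c(carb = 52, fat = 30, protein = 18),
                             deficit = 0.15, floor = 1200,
                             amdr = default_amdr(),
                             constants = read_eer_constants()) {
  goal <- match.arg(goal)
  pa <- if (is.null(activity)) 1.0 else activity$pa_coefficient
  eer <- estimate_eer(sex, age_years, weight, height / 100, pa, constants)
  target <- apply_goal(eer, goal, deficit = deficit, floor = floor)
  structure(
    list(
      eer = eer, goal = goal, target_energy = target,
      macros = macronutrient_targets(target, split, amdr)
    ),
    class = "energy_prescription"
  )
}

#' @export
print.energy_prescription <- function(x, ...) {
  cat(sprintf(
    "EER %.0f kcal/day | goal %s | target %.0f kcal/day\n",
    x$eer, x$goal, x$target_energy
  ))
  for (i in seq_len(nrow(x$macros))) {
    cat(sprintf(
      "  %-8s %5.1f%%  %6.1f g/day\n",
      x$macros$macro[i], x$macros$pct[i], x$macros$grams[i]
    ))
  }
  invisible(x)
}
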