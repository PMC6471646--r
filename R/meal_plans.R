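# Macronutrient grams contributed by one exchange of each food group
# (standard food-exchange-list composition; milk as reduced-fat, meat as
# medium-fat equivalents).
EXCHANGE_MACROS <- list(
  starch    = c(carb = 15, fat = 1, protein = 3),
  fruit     = c(carb = 15, fat = 0, protein = 0),
  vegetable = c(carb = 5, fat = 0, protein = 2),
  milk      = c(carb = 12, fat = 5, protein = 8),
  meat      = c(carb = 0, fat = 5, protein = 7),
  fat       = c(carb = 0, fat = 5, protein = 0),
  sweets    = c(carb = 15, fat = 0, protein = 0)
)

macros_from_counts <- function(counts) {
  g <- c(carb = 0, fat = 0, protein = 0)
  for (grp in names(counts)) {
    comp <- EXCHANGE_MACROS[[grp]]
    if (is.null(comp)) {
      stop("unknown exchange group '", grp, "'", call. = FALSE)
    }
    g <- g + counts[[grp]] * comp
  }
  g
}

#' Read a weekly meal-plan template
#'
#' Templates are exchange-based: daily counts per food group at a reference
#' energy, plus machine-checkable composition constraints (maximum percent
#' of energy from sucrose, minimum fibre density, maximum sodium density)
#' distinguishing the fibre-rich / low-simple-sugar plans (2 and 4) from the
#' standard plans (1 and 3). Plans 1-2 are isocaloric (weight maintenance),
#' plans 3-4 hypocaloric (mild weight loss).
#'
#' @param path YAML file with `id`, `goal`, `reference_energy`,
#'   `granularity`, `exchanges` (named counts) and `constraints`.
#' @return Object of class `meal_plan_template`.
#' @export
read_meal_plan <- function(path) {
  if (!file.exists(path)) {
    stop("meal-plan template not found: ", path, call. = FALSE)
  }
  x <- yaml::read_yaml(path)
  stopifnot(
    !is.null(x$id), !is.null(x$reference_energy),
    !is.null(x$exchanges), length(x$exchanges) > 0
  )
  if (x$reference_energy <= 0) {
    stop("reference_energy must be positive", call. = FALSE)
  }
  if (is.null(x$granularity)) x$granularity <- 0.5
  structure(x, class = "meal_plan_template")
}

#' Load the packaged meal-plan templates
#'
#' @param dir Directory of `mp*.yaml` templates; defaults to the packaged
#'   set (MP1-MP4).
#' @return Named list of `meal_plan_template` objects keyed by id.
#' @export
load_meal_plans <- function(dir = system.file("extdata", "meal_plans",
                              package = "peddst"
                            )) {
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  if (!length(files)) {
    stop("no meal-plan templates found in ", dir, call. = FALSE)
  }
  plans <- lapply(files, read_meal_plan)
  names(plans) <- vapply(plans, function(p) p$id, character(1))
  plans
}

#' Scale a meal-plan template to a target energy
#'
#' Exchange counts are scaled proportionally by
#' `target_energy / reference_energy`, rounded to the template's granularity
#' (default half an exchange), and the post-rounding macronutrient split is
#' re-checked against the AMDRs; violations beyond the tolerance are
#' recorded as warnings in the returned object (for the report), not raised.
#'
#' @param template A `meal_plan_template`.
#' @param target_energy Target energy, kcal/day, strictly positive.
#' @param amdr AMDR bounds, as from [default_amdr()].
#' @param tolerance Allowed AMDR overshoot after rounding, percentage
#'   points (default 2).
#' @return Object of class `scaled_meal_plan`: list with `plan_id`,
#'   `counts` (rounded daily exchanges), `scale_factor`, `energy_kcal` (as
#'   delivered by the rounded counts), `macro_pct`, `warnings`.
#' @export
scale_meal_plan <- function(template, target_energy, amdr = default_amdr(),
                            tolerance = 2) {
  stopifnot(inherits(template, "meal_plan_template"))
  if (!is.finite(target_energy) || target_energy <= 0) {
    stop("`target_energy` must be strictly positive", call. = FALSE)
  }
  factor <- target_energy / template$reference_energy
  g <- template$granularity
  counts <- lapply(template$exchanges, function(n) round(n * factor / g) * g)
  grams <- macros_from_counts(counts)
  kcal <- sum(grams * ATWATER[names(grams)])
  pct <- 100 * grams * ATWATER[names(grams)] / kcal
  warn <- character(0)
  for (m in names(pct)) {
    b <- amdr[[m]]
    if (pct[[m]] < b[1] - tolerance || pct[[m]] > b[2] + tolerance) {
      warn <- c(warn, sprintf(
        "%s at %.1f%% of energy outside AMDR [%g%%, %g%%] after rounding",
        m, pct[[m]], b[1], b[2]
      ))
    }
  }
  structure(
    list(
      plan_id = template$id, counts = counts, scale_factor = factor,
      energy_kcal = kcal, macro_pct = pct, warnings = warn
    ),
    class = "scaled_meal_plan"
  )
}

#' @export
print.scaled_meal_plan <- function(x, ...) {
  cat(sprintf(
    "%s scaled x%.3f -> %.0f kcal/day\n", x$plan_id, x$scale_factor,
    x$energy_kcal
  ))
  cat("  exchanges/day:", paste(sprintf(
    "%s %.1f", names(x$counts),
    unlist(x$counts)
  ), collapse = ", "), "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
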