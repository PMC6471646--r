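DISORDER_FLAGS <- c(
  "hyperglycaemia", "insulin_resistance", "dyslipidaemia",
  "hypertension"
)

#' Construct and validate a child record
#'
#' One child's demographic, anthropometric, activity, clinical-flag and
#' (optional) perinatal data at one visit.
#'
#' @param id Child identifier.
#' @param sex "male" or "female".
#' @param birth_date,exam_date ISO-8601 dates; examination must not precede
#'   birth.
#' @param weight,height Measurement in kg / cm, strictly positive.
#' @param measurement_mode "standing_height" or "recumbent_length";
#'   recumbent length only below 24 months of age.
#' @param activity_category "light", "moderate" or "vigorous" (MET-based).
#' @param disorders Named logical vector over `hyperglycaemia`,
#'   `insulin_resistance`, `dyslipidaemia`, `hypertension` (clinician
#'   supplied flags; missing names default to FALSE).
#' @param waist Optional waist circumference in cm, strictly positive.
#' @param perinatal Optional named list of CORE inputs
#'   (`infant_weight_birth`, `infant_weight_6mo`,
#'   `maternal_smoking_pregnancy`, `maternal_prepregnancy_bmi`,
#'   `maternal_education`).
#' @return Object of class `child_record`.
#' @export
child_record <- function(id, sex, birth_date, exam_date, weight, height,
                         measurement_mode = "standing_height",
                         activity_category = "light",
                         disorders = NULL, waist = NULL, perinatal = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  measurement_mode <- match.arg(
    measurement_mode,
    c("standing_height", "recumbent_length")
  )
  activity_category <- match.arg(
    activity_category,
    c("light", "moderate", "vigorous")
  )
  age <- age_in_months(birth_date, exam_date) # validates order
  if (measurement_mode == "recumbent_length" && age$months >= 24) {
    stop("recumbent length is only valid below 24 months of age", call. = FALSE)
  }
  if (!is.finite(weight) || weight <= 0) {
    stop("`weight` must be strictly positive (kg)", call. = FALSE)
  }
  if (!is.finite(height) || height <= 0) {
    stop("`height` must be strictly positive (cm)", call. = FALSE)
  }
  if (!is.null(waist) && !is.na(waist) && waist <= 0) {
    stop("`waist` must be strictly positive (cm) when present", call. = FALSE)
  }
  flags <- stats::setNames(rep(FALSE, 4), DISORDER_FLAGS)
  if (!is.null(disorders)) {
    unknown <- setdiff(names(disorders), DISORDER_FLAGS)
    if (length(unknown)) {
      stop("unknown disorder flag(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    flags[names(disorders)] <- vapply(disorders, isTRUE, logical(1))
  }
  structure(
    list(
      id = as.character(id), sex = sex,
      birth_date = as.character(as.Date(birth_date)),
      exam_date = as.character(as.Date(exam_date)),
      weight = weight, height = height,
      measurement_mode = measurement_mode,
      activity_category = activity_category,
      disorders = flags,
      waist = if (is.null(waist) || is.na(waist)) NA_real_ else waist,
      perinatal = perinatal,
      age_months = age$months, age_years = age$years
    ),
    class = "child_record"
  )
}

#' Construct and validate a parent record
#'
#' Parents are categorised as obese exactly when BMI > 30 kg/m^2 (strict
#' inequality). Anthropometry may be measured or self-reported; the source
#' is carried as a flag and not differentially processed.
#'
#' @param role "mother" or "father".
#' @param weight,height kg / cm, strictly positive.
#' @param education_years Optional years of education (recorded for the
#'   mother; a CORE component).
#' @param source "measured" or "reported".
#' @return Object of class `parent_record` with derived `bmi` and `obese`.
#' @export
parent_record <- function(role, weight, height, education_years = NA,
                          source = c("measured", "reported")) {
  role <- match.arg(role, c("mother", "father"))
  source <- match.arg(source)
  bmi <- compute_bmi(weight, height)
  structure(
    list(
      role = role, weight = weight, height = height,
      education_years = as.numeric(education_years),
      bmi = bmi, obese = bmi > 30, source = source
    ),
    class = "parent_record"
  )
}

#' @export
print.child_record <- function(x, ...) {
  cat(sprintf(
    "child %s (%s), %.1f months, %.1f kg, %.1f cm\n",
    x$id, x$sex, x$age_months, x$weight, x$height
  ))
  invisible(x)
}

#' @export
print.parent_record <- function(x, ...) {
  cat(sprintf(
    "%s: BMI %.1f (%s)\n", x$role, x$bmi,
    if (x$obese) "obese" else "non-obese"
  ))
  invisible(x)
}

family_from_list <- function(x) {
  ch <- x$child
  if (is.null(ch)) stop("family entry lacks a `child` object", call. = FALSE)
  perinatal <- ch$perinatal
  if (!is.null(perinatal)) {
    perinatal <- list(
      child_sex = ch$sex,
      infant_weight_birth = perinatal$birth_weight_kg,
      infant_weight_6mo = perinatal$weight_6mo_kg,
      maternal_smoking_pregnancy = perinatal$maternal_smoking_pregnancy,
      maternal_prepregnancy_bmi = perinatal$maternal_prepregnancy_bmi,
      maternal_education = perinatal$maternal_education_years
    )
  }
  child <- child_record(
    id = ch$id, sex = ch$sex,
    birth_date = ch$birth_date, exam_date = ch$exam_date,
    weight = ch$weight_kg, height = ch$height_cm,
    measurement_mode = if (is.null(ch$measurement_mode)) {
      "standing_height"
    } else {
      ch$measurement_mode
    },
    activity_category = if (is.null(ch$activity_category)) {
      "light"
    } else {
      ch$activity_category
    },
    disorders = ch$disorders,
    waist = ch$waist_cm,
    perinatal = perinatal
  )
  parents <- list()
  for (role in c("mother", "father")) {
    p <- x[[role]]
    if (!is.null(p)) {
      parents[[role]] <- parent_record(
        role = role, weight = p$weight_kg, height = p$height_cm,
        education_years = if (is.null(p$education_years)) NA else p$education_years,
        source = if (is.null(p$source)) "measured" else p$source
      )
    }
  }
  list(child = child, parents = parents)
}

csv_row_to_family <- function(row) {
  num <- function(col) {
    if (!col %in% names(row) || is.na(row[[col]])) NULL else as.numeric(row[[col]])
  }
  bool <- function(col) {
    if (!col %in% names(row) || is.na(row[[col]])) {
      NULL
    } else {
      as.logical(row[[col]])
    }
  }
  chr <- function(col) {
    if (!col %in% names(row) || is.na(row[[col]]) || row[[col]] == "") {
      NULL
    } else {
      as.character(row[[col]])
    }
  }
  x <- list(
    child = list(
      id = chr("child_id"), sex = chr("child_sex"),
      birth_date = chr("birth_date"), exam_date = chr("exam_date"),
      weight_kg = num("weight_kg"), height_cm = num("height_cm"),
      measurement_mode = chr("measurement_mode"),
      activity_category = chr("activity_category"),
      waist_cm = num("waist_cm"),
      disorders = Filter(Negate(is.null), list(
        hyperglycaemia = bool("hyperglycaemia"),
        insulin_resistance = bool("insulin_resistance"),
        dyslipidaemia = bool("dyslipidaemia"),
        hypertension = bool("hypertension")
      )),
      perinatal = list(
        birth_weight_kg = num("birth_weight_kg"),
        weight_6mo_kg = num("weight_6mo_kg"),
        maternal_smoking_pregnancy = bool("maternal_smoking_pregnancy"),
        maternal_prepregnancy_bmi = num("maternal_prepregnancy_bmi"),
        maternal_education_years = num("maternal_education_years")
      )
    )
  )
  if (!is.null(num("mother_weight_kg")) && !is.null(num("mother_height_cm"))) {
    x$mother <- list(
      weight_kg = num("mother_weight_kg"),
      height_cm = num("mother_height_cm"),
      education_years = num("maternal_education_years")
    )
  }
  if (!is.null(num("father_weight_kg")) && !is.null(num("father_height_cm"))) {
    x$father <- list(
      weight_kg = num("father_weight_kg"),
      height_cm = num("father_height_cm")
    )
  }
  x
}

#' Load family records from JSON or CSV
#'
#' JSON files hold one family object (`child`, optional `mother`,
#' `father`) or a list of them; CSV files hold one family per row in the
#' documented header dialect (child, perinatal, mother and father columns;
#' see the packaged `example_families.csv`). Rows that fail validation are
#' collected with their identifier and message; valid rows are still
#' returned.
#'
#' @param path File path.
#' @param format "auto" (by extension), "json" or "csv".
#' @return List with `families` (each a list of `child` and `parents`) and
#'   `errors` (data.frame of `index`, `id`, `message`).
#' @export
load_records <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- if (format == "json") {
    x <- jsonlite::read_json(path)
    if (!is.null(x$child)) list(x) else x
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) csv_row_to_family(df[i, , drop = FALSE]))
  }
  families <- list()
  errors <- data.frame(
    index = integer(0), id = character(0),
    message = character(0)
  )
  for (i in seq_along(raw)) {
    id <- tryCatch(as.character(raw[[i]]$child$id), error = function(e) NA_character_)
    fam <- tryCatch(family_from_list(raw[[i]]), error = function(e) e)
    if (inherits(fam, "error")) {
      errors <- rbind(errors, data.frame(
        index = i, id = if (length(id)) id else NA_character_,
        message = conditionMessage(fam)
      ))
    } else {
      families[[length(families) + 1L]] <- fam
    }
  }
  list(families = families, errors = errors)
}
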