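#' Infant weight gain over the first six months
#'
#' Difference between the child-health-record weights at six months and at
#' birth, the rapid-early-growth component of the obesity-risk score.
#' Missing inputs propagate as `NA` so the scorer can apply its
#' missing-data policy.
#'
#' @param birth Weight at birth, kg.
#' @param six_mo Weight at six months, kg.
#' @return Gain in kg, or `NA` if either weight is missing.
#' @export
weight_gain_0_6mo <- function(birth, six_mo) {
  if (is.null(birth) || is.null(six_mo) || is.na(birth) || is.na(six_mo)) {
    return(NA_real_)
  }
  if (birth <= 0 || six_mo <= 0) {
    stop("weights must be strictly positive (kg)", call. = FALSE)
  }
  if (six_mo < 0.5 * birth) {
    stop("six-month weight below half the birth weight: implausible record",
      call. = FALSE
    )
  }
  six_mo - birth
}

#' Read a CORE score table from a YAML config
#'
#' The CORE (Childhood Obesity Risk Evaluation) index combines perinatal and
#' socio-demographic risk factors into an integer score. The published
#' index defines the components and the high-risk threshold (score >= 4),
#' but its point assignments live in separately published validation work,
#' so the point table is runtime configuration. The
#' packaged default (`core_default.yaml`) is a documented placeholder with
#' plausible bins, not the published coefficients.
#'
#' Each component maps one input field through ordered bins to non-negative
#' integer points. Numeric bins are left-closed, right-open `[min, max)`
#' (omitted bounds are infinite); boolean and categorical bins match by
#' value. Bins must be mutually exclusive and exhaustive.
#'
#' @param path YAML file path.
#' @return Object of class `core_score_table`.
#' @export
read_core_table <- function(path) {
  if (!file.exists(path)) {
    stop("CORE table not found: ", path, call. = FALSE)
  }
  as_core_table(yaml::read_yaml(path))
}

#' Construct a CORE score table from a list
#'
#' @param x List with `threshold` (integer, default 4), optional
#'   `missing_policy` ("zero_points" or "refuse", default "zero_points"),
#'   and `components`: a list of `{name, field, type, bins}` entries (see
#'   [read_core_table()]).
#' @return A validated `core_score_table`.
#' @export
as_core_table <- function(x) {
  if (is.null(x$components) || !length(x$components)) {
    stop("CORE table must define at least one component", call. = FALSE)
  }
  threshold <- if (is.null(x$threshold)) 4L else as.integer(x$threshold)
  missing_policy <- if (is.null(x$missing_policy)) "zero_points" else x$missing_policy
  missing_policy <- match.arg(missing_policy, c("zero_points", "refuse"))
  for (comp in x$components) {
    if (is.null(comp$name) || is.null(comp$field) || is.null(comp$type) ||
      is.null(comp$bins) || !length(comp$bins)) {
      stop("each CORE component needs name, field, type and bins", call. = FALSE)
    }
    comp$type <- match.arg(comp$type, c("numeric", "boolean", "category"))
    pts <- vapply(comp$bins, function(b) as.numeric(b$points), numeric(1))
    if (any(is.na(pts)) || any(pts < 0) || any(pts != round(pts))) {
      stop("CORE points must be non-negative integers (component '",
        comp$name, "')",
        call. = FALSE
      )
    }
    if (comp$type == "numeric") {
      lo <- vapply(comp$bins, function(b) {
        if (is.null(b$min)) -Inf else as.numeric(b$min)
      }, numeric(1))
      hi <- vapply(comp$bins, function(b) {
        if (is.null(b$max)) Inf else as.numeric(b$max)
      }, numeric(1))
      o <- order(lo)
      if (!is.infinite(lo[o][1]) || !is.infinite(hi[o][length(hi)]) ||
        any(hi[o][-length(hi)] != lo[o][-1])) {
        stop("numeric CORE bins must tile (-Inf, Inf) without gaps or ",
          "overlaps (component '", comp$name, "')",
          call. = FALSE
        )
      }
    }
  }
  max_score <- sum(vapply(x$components, function(comp) {
    max(vapply(comp$bins, function(b) as.numeric(b$points), numeric(1)))
  }, numeric(1)))
  structure(
    list(
      components = x$components, threshold = threshold,
      missing_policy = missing_policy, max_score = as.integer(max_score)
    ),
    class = "core_score_table"
  )
}

#' @export
print.core_score_table <- function(x, ...) {
  cat(sprintf(
    "CORE score table: %d components, max score %d, threshold >= %d, missing -> %s\n",
    length(x$components), x$max_score, x$threshold, x$missing_policy
  ))
  invisible(x)
}

# Points for one component given the input value; NA signals a missing value.
score_component <- function(comp, value) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) {
    return(NA_integer_)
  }
  for (b in comp$bins) {
    hit <- switch(comp$type,
      numeric = {
        lo <- if (is.null(b$min)) -Inf else as.numeric(b$min)
        hi <- if (is.null(b$max)) Inf else as.numeric(b$max)
        value >= lo && value < hi
      },
      boolean = isTRUE(value) == isTRUE(b$value),
      category = identical(as.character(value), as.character(b$value))
    )
    if (isTRUE(hit)) {
      return(as.integer(b$points))
    }
  }
  stop("CORE component '", comp$name, "': value ", deparse(value),
    " matches no bin (configuration error)",
    call. = FALSE
  )
}

#' Score the CORE index for one child
#'
#' Sums the per-component points of the score table over the supplied
#' inputs. The derived component `weight_gain_0_6mo` is computed from
#' `infant_weight_birth` and `infant_weight_6mo` when the table references
#' it. Missing components follow the table's missing policy: `zero_points`
#' contributes 0 and is counted in `n_missing`; `refuse` raises an error.
#'
#' The index is designed for currently normal-weight children (the
#' prevention pathway); scoring a child of another weight status is allowed
#' but flagged `out_of_pathway`.
#'
#' @param inputs Named list of CORE inputs: `child_sex`,
#'   `maternal_prepregnancy_bmi` (or a category string, depending on the
#'   table), `maternal_smoking_pregnancy`, `infant_weight_birth`,
#'   `infant_weight_6mo`, `maternal_education`. Any field may be `NA`.
#' @param table A `core_score_table`.
#' @param weight_status Optional current weight-status category used only to
#'   set the `out_of_pathway` flag.
#' @return Object of class `core_result`: list with `score`, `components`
#'   (named integer vector), `n_missing`, `classification`,
#'   `out_of_pathway`.
#' @export
score_core <- function(inputs, table, weight_status = "normal") {
  stopifnot(inherits(table, "core_score_table"))
  vals <- inputs
  vals$weight_gain_0_6mo <- weight_gain_0_6mo(
    inputs$infant_weight_birth, inputs$infant_weight_6mo
  )
  pts <- integer(0)
  n_missing <- 0L
  for (comp in table$components) {
    v <- vals[[comp$field]]
    p <- score_component(comp, v)
    if (is.na(p)) {
      if (table$missing_policy == "refuse") {
        stop("CORE component '", comp$name, "' is missing and policy is 'refuse'",
          call. = FALSE
        )
      }
      n_missing <- n_missing + 1L
      p <- 0L
    }
    pts[comp$name] <- p
  }
  score <- sum(pts)
  structure(
    list(
      score = as.integer(score), components = pts, n_missing = n_missing,
      classification = classify_core(score, table$threshold),
      out_of_pathway = !identical(weight_status, "normal")
    ),
    class = "core_result"
  )
}

#' Classify future-obesity likelihood from a CORE score
#'
#' A score at or above the threshold (default 4) flags a higher likelihood
#' of future obesity manifestation.
#'
#' @param score Non-negative integer CORE score.
#' @param threshold Classification threshold, default 4.
#' @return "higher_likelihood" or "lower_likelihood".
#' @export
classify_core <- function(score, threshold = 4L) {
  if (any(!is.finite(score)) || any(score < 0)) {
    stop("`score` must be non-negative", call. = FALSE)
  }
  ifelse(score >= threshold, "higher_likelihood", "lower_likelihood")
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf(
    "CORE score %d (%s)%s; %d component(s) missing\n",
    x$score, x$classification,
    if (x$out_of_pathway) " [out of pathway]" else "", x$n_missing
  ))
  invisible(x)
}

#' Path to the packaged placeholder CORE table
#' @return File path of `core_default.yaml`.
#' @export
default_core_table_path <- function() {
  system.file("extdata", "core_default.yaml", package = "peddst")
}
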