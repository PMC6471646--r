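#' Within-group change score
#'
#' The change from baseline to follow-up: `followup_mean - baseline_mean`.
#'
#' @param baseline_mean,followup_mean Group means in the variable's units.
#' @return The change, exact arithmetic.
#' @examples
#' change_score(16.0, 11.4) # sucrose g/day, intervention group
#' @export
change_score <- function(baseline_mean, followup_mean) {
  stopifnot(is.finite(baseline_mean), is.finite(followup_mean))
  followup_mean - baseline_mean
}

#' Between-group difference of change scores
#'
#' Intervention-group change minus control-group change.
#'
#' @param ig_change,cg_change Within-group changes.
#' @return `ig_change - cg_change`, exact arithmetic.
#' @export
between_group_difference <- function(ig_change, cg_change) {
  stopifnot(is.finite(ig_change), is.finite(cg_change))
  ig_change - cg_change
}

#' Attrition between enrolment and analysis
#'
#' @param n_enrolled,n_analysed Counts; `n_analysed` cannot exceed
#'   `n_enrolled`.
#' @return List with `dropped` and `rate` (percent of those enrolled).
#' @examples
#' attrition(80, 65)
#' @export
attrition <- function(n_enrolled, n_analysed) {
  if (n_analysed > n_enrolled) {
    stop("`n_analysed` cannot exceed `n_enrolled`", call. = FALSE)
  }
  if (n_enrolled <= 0) {
    stop("`n_enrolled` must be positive", call. = FALSE)
  }
  dropped <- n_enrolled - n_analysed
  list(dropped = dropped, rate = 100 * dropped / n_enrolled)
}

#' Enrolment needed for a target analysed sample under planned attrition
#'
#' Inverse of [attrition()]: to retain `n_required` participants with an
#' anticipated attrition fraction `rate`, enrol `n_required / (1 - rate)`,
#' rounded up.
#'
#' @param n_required Analysed sample size required by the power
#'   calculation.
#' @param rate Planned attrition as a fraction in `[0, 1)`.
#' @return Enrolment count (integer).
#' @examples
#' plan_enrolment(64, 0.20)
#' @export
plan_enrolment <- function(n_required, rate) {
  if (!is.finite(rate) || rate < 0 || rate >= 1) {
    stop("`rate` must lie in [0, 1)", call. = FALSE)
  }
  if (n_required <= 0) {
    stop("`n_required` must be positive", call. = FALSE)
  }
  as.integer(ceiling(n_required / (1 - rate)))
}

#' Read a trial summary-means table
#'
#' Reads a TSV of printed group means (`variable`, `group`,
#' `baseline_mean`, `followup_mean`) such as the packaged
#' `trial_summary.tsv`, and derives the change scores and the
#' intervention-minus-control differences.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return List with `means` (the input plus a `change` column) and
#'   `differences` (named vector of IG - CG change differences per
#'   variable).
#' @export
read_trial_summary <- function(path = system.file("extdata", "trial_summary.tsv",
                                 package = "peddst"
                               )) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variable", "group", "baseline_mean", "followup_mean") %in% names(df)))
  df$change <- mapply(change_score, df$baseline_mean, df$followup_mean)
  vars <- unique(df$variable)
  diffs <- vapply(vars, function(v) {
    ig <- df$change[df$variable == v & df$group == "IG"]
    cg <- df$change[df$variable == v & df$group == "CG"]
    if (length(ig) == 1 && length(cg) == 1) {
      between_group_difference(ig, cg)
    } else {
      NA_real_
    }
  }, numeric(1))
  list(means = df, differences = diffs)
}
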