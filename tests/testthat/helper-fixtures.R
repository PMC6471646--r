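# Shared fixtures, built in code.

pkg_lms <- function() {
  read_lms_table(system.file("extdata", "lms_synthetic.tsv", package = "peddst"))
}

# Tiny hand-made LMS table with easy-to-reason-about knots.
toy_lms <- function() {
  as_lms_table(data.frame(
    sex = rep("male", 3),
    age_months = c(60, 120, 180),
    L = c(1.0, 2.0, -1.0),
    M = c(16.0, 17.0, 20.0),
    S = c(0.10, 0.12, 0.13)
  ))
}

# Three-component toy CORE table with points (2, 1, 1) when triggered.
toy_core <- function(threshold = 4) {
  as_core_table(list(
    threshold = threshold,
    components = list(
      list(
        name = "a", field = "a", type = "boolean",
        bins = list(
          list(value = TRUE, points = 2),
          list(value = FALSE, points = 0)
        )
      ),
      list(
        name = "b", field = "b", type = "boolean",
        bins = list(
          list(value = TRUE, points = 1),
          list(value = FALSE, points = 0)
        )
      ),
      list(
        name = "c", field = "c", type = "boolean",
        bins = list(
          list(value = TRUE, points = 1),
          list(value = FALSE, points = 0)
        )
      )
    )
  ))
}

demo_family <- function() {
  load_records(system.file("extdata", "example_family.json",
    package = "peddst"
  ))$families[[1]]
}
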