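Package: peddst
Title: Decision-Support Tool for Paediatric Overweight and Obesity Management
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computerised decision-support tool for paediatric healthcare
    professionals working on childhood overweight and obesity prevention and
    treatment. Provides BMI-for-age assessment against LMS growth references,
    a configurable perinatal obesity-risk score (CORE index) for normal-weight
    children, Institute of Medicine estimated-energy-requirement equations
    with acceptable-macronutrient-distribution-range planning, exchange-based
    meal-plan scaling, a fully enumerated decision tree mapping child state to
    recommendation level, meal plan, target population and re-evaluation
    interval, clinician-facing report generation in JSON and Markdown, and a
    seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
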