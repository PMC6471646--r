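---
title: "Methods: paediatric weight-management decision support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paediatric weight-management decision support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peddst)
```

## Overview

`peddst` implements a computerised decision-support tool for paediatric
healthcare professionals managing childhood overweight and obesity. A
single visit is processed in five stages:

1. **Weight-status assessment.** BMI (Quetelet's equation) is located on a
   sex- and age-specific BMI-for-age reference via the LMS transform, and
   the percentile classifies the child as underweight (< 5th), normal
   (5th–85th), overweight (85th–95th) or obese (>= 95th), with all
   intervals left-closed.
2. **Future-obesity risk.** Normal-weight children are scored with the
   CORE (Childhood Obesity Risk Evaluation) index, an integer score over
   perinatal and socio-demographic factors; a score >= 4 flags a higher
   likelihood of later obesity.
3. **Weight-management goal.** Maintenance (isocaloric) for overweight
   children and obese 2–5-year-olds; mild weight loss (hypocaloric) for
   obese 6–15-year-olds.
4. **Energy and macronutrient planning.** IOM estimated-energy-requirement
   equations with physical-activity coefficients, a goal-adjusted energy
   target, macronutrient percentages inside the AMDRs converted to grams
   with 4/9/4 Atwater factors, and an exchange-based meal plan scaled to
   the target.
5. **Reporting.** A deterministic report with items (a)–(f): weight
   status and goal, risk classification, energy requirement,
   macronutrient needs, meal plan, and recommendations with
   behavioural-change goals.

## The growth-reference model

The LMS (lambda–mu–sigma) transform maps a measurement $x$ at a given age
and sex to a z-score

$$z = \frac{(x/M)^L - 1}{L\,S}, \qquad L \neq 0,$$

with the limit $z = \log(x/M)/S$ as $L \to 0$; the log branch is taken for
$|L| \le 10^{-8}$, where the two branches agree to well below $10^{-9}$.
Percentiles use the exact standard-normal CDF rather than a rational
approximation, so boundary behaviour is testable to machine precision. L,
M and S are interpolated linearly in age, independently of one another,
and lookups outside the table's age range are errors — the reference is
never extrapolated. Absolute z-scores above 5 are flagged with a warning
but not capped, since no plausibility capping is part of the published
procedure.

The packaged table `lms_synthetic.tsv` is a **synthetic** reference:
smooth, monotone curves with an infancy peak, a mid-childhood adiposity
rebound and an adolescent rise, constructed so that a realistic
overweight/obese school-age cohort (mean BMI around 25 kg/m², roughly 60%
obese) sits inside the plausible z range. It is not the WHO reference;
real WHO/CDC LMS tables in the same four-column TSV layout are a drop-in
replacement for clinical use.

Ages are computed from the birth and examination dates as day counts
divided by 30.4375 (the mean Gregorian month), with whole years the
integer truncation of months/12.

## The CORE score as configuration

The published tool names the CORE components — child sex, maternal
pre-pregnancy weight status, maternal smoking in pregnancy, infant weight
gain over the first six months, maternal education — and the >= 4
threshold, but not the point assignments, which live in separately
published work. The score table is therefore **runtime configuration**: a
YAML file mapping each component through ordered, mutually exclusive and
exhaustive bins to non-negative integer points. The packaged
`core_default.yaml` is a documented placeholder with plausible bins (for
example, 2 points for a six-month weight gain of 4 kg or more), not the
published coefficients. Numeric bins are left-closed `[min, max)`; the
format accepts either a continuous maternal pre-pregnancy BMI or a
category string, so either predicate style can be configured without code
changes.

Missing components follow a configurable policy: `zero_points` (default)
contributes nothing and increments the reported `n_missing`;
`refuse` raises an error. No imputation is performed, as none is
described for the tool. The index is computed for normal-weight children
(the prevention pathway); scoring any other child is allowed but flagged
`out_of_pathway`.

## Energy prescription

EER coefficients live in a versioned constants file
(`eer_constants.yaml`) covering three bands: 0–35 months
($89w - 100$ plus an age-specific deposition energy), 3–8 years and
9–18 years (sex-specific linear equations with the physical-activity
coefficient multiplying the weight/height term; heights in metres
inside the equations, converted from cm at the interface). Ages of 19
years and over raise an explicit unsupported-band error. Measured weight
is used for obese children as well — the published procedure does not
mention an ideal or adjusted weight — and the report records this.

The clinical activity taxonomy is MET-based (light < 4, moderate 4–7,
vigorous > 7 METs) while the IOM equations use PA levels. The bridge is
configuration with a conservative default (light -> sedentary 1.00,
moderate -> low active, vigorous -> active), since no published mapping
exists for the tool.

The magnitude of "mild weight loss" is also unstated; the default is a
15% deficit off the EER, configurable, with a safety floor of 1200
kcal/day. A configured deficit whose target falls below the floor is an
**error**, not a silent clamp — prescriptions should fail loudly rather
than be quietly adjusted.

Macronutrient splits are validated against the AMDRs (carbohydrate
45–65%, fat 25–35%, protein 10–30% of energy, the 4–18-year ranges; the
under-4 AMDR differences are out of scope) and must sum to 100 ± 0.01.
Grams use the 4/9/4 Atwater factors, so energy is conserved to well
under 0.5 kcal before rounding.

Meal plans 1–4 are exchange-based templates (daily counts per food group
at a reference energy) with machine-checkable composition constraints —
maximum percent of energy from sucrose, minimum fibre density, maximum
sodium density — distinguishing the fibre-rich/low-sugar plans (2 and 4)
from the standard plans (1 and 3). The literal weekly menus are not part
of the artifact; the constraints make the plan distinction testable.
Scaling multiplies counts by `target/reference`, rounds to the template
granularity (half an exchange by default), and re-checks the
post-rounding macronutrient split against the AMDRs; violations beyond 2
percentage points become report warnings rather than errors, because
rounding distortion at low energies is expected and the clinician should
see it.

## The decision tree

The engine routes on five coordinates: age band (under 2, 2–5, 6–15,
over 15 years), weight status, CORE classification (normal-weight
children only), at least one clinical disorder (the four flags collapsed
by OR, as phrased in the published pathway; individual flags are still
carried to the report), and at least one obese parent (BMI strictly
greater than 30 kg/m²). The recommendation level follows a single 2×2
grid on (disorder, obese parent): R1, R2, R3, R4, with R2/R4 targeting
the whole family. Overweight children (and obese 2–5-year-olds, who
follow the same pathway) receive isocaloric plan 1 or 2; obese
6–15-year-olds receive hypocaloric plan 3 or 4 with mild weight loss.
Re-evaluation intervals are 6/12 months for normal-weight children and
3/6 months otherwise, the shorter interval when a disorder or an obese
parent is present ("and/or" read as OR; an AND reading would change two
cells, which the tests document by asserting the OR semantics
explicitly).

Three design points were genuinely open:

* **The obese 6–15 cell with no disorder and non-obese parents** is never
  stated in the published pathway. The engine fills it by symmetry with
  the overweight grid (R1 + plan 3, mild loss, 6-month review) and flags
  the outcome `inferred_cell = TRUE` so no consumer can mistake it for
  published text.
* **Underweight children, 16-and-overs, and obese under-2s** fall outside
  every printed pathway and produce an explicit `refer` outcome (no plan,
  no interval) instead of an error, keeping `decide()` total over the
  80-state space. Overweight under-2s are routed through the overweight
  pathway, which the published description does not age-restrict.
* **Re-evaluation is memoryless**: every published transition sentence
  routes on the new BMI percentile alone, so `reevaluate()` equals
  `decide()` on the new state, retaining the previous outcome only for
  the report's trajectory. CORE is re-scored for children who have become
  normal weight.

## The synthetic cohort

`generate_cohort()` emulates the baseline population of the evaluation
trial: 6–12-year-old overweight/obese children (mean age 9.7 y, mean BMI
25.1 kg/m², 60.7% obese), parents with mean BMI 28.6 (fathers) and 27.3
(mothers), mean birth weight 3.2 kg, mean activity 21.6 min/day, mean
maternal pre-pregnancy BMI 24.9 kg/m². Only means, SEMs and percentages
are published, so distribution shapes are a design choice: truncated
normals for continuous variables (SD = SEM·sqrt(65), the analysed sample
size) and Bernoulli draws for flags. The generator's contract is
**moment matching**, not distributional fidelity: the pre-truncation
location is calibrated by root-finding on the analytic truncated-normal
mean so the post-truncation expectation equals the target even when
truncation binds (it binds strongly for activity minutes, whose SD of
about 18.5 min/day pushes mass below zero).

Each child's weight-status class is drawn first (Bernoulli on the obese
fraction), then BMI inside that class's percentile band of the reference
table (between the 85th and 95th percentiles for overweight; above the
95th, bounded at z = 4 for plausibility, for obese), so a degenerate
spec with obese fraction 1 yields a cohort entirely at or above the 95th
percentile. Height follows an age-linked growth line and weight is
derived from BMI, so anthropometry is internally consistent.

Values with no published counterpart are fixed, realistic choices:
maternal smoking in pregnancy 30%, activity categories 50/40/10%
light/moderate/vigorous, disorder prevalences 5–15%, parental heights
164 ± 6 and 177 ± 7 cm, six-month weight gain 4.0 ± 1.0 kg, education
years 8/11/16 with the published category percentages. What the
generator does **not** emulate: within-family correlation beyond the
height–age and waist–BMI links, secular trends, measurement error, or
any intervention response — passing cohort tests therefore demonstrates
the pipeline's behaviour on a realistic population, not clinical
validity on real records.

The deterministic change-score arithmetic of the evaluation
(follow-up minus baseline within groups; intervention minus control
between groups; attrition and enrolment planning) is provided as exact
functions; the repeated-measures inference of the original analysis is
deliberately not reimplemented, as it requires the raw trial data.

## Numerical choices and problem sizes

* Log-branch threshold $|L| \le 10^{-8}$; branch continuity and the
  z-score round-trip are verified to $10^{-9}$.
* Percentile boundaries (5/85/95) are left-closed exactly as printed;
  classification is monotone in the percentile.
* Truncated-normal sampling uses the inverse-CDF method; the calibration
  root-finder brackets the root by the extreme truncation bounds and the
  tail-stable truncated-mean evaluation switches to a Mills-ratio
  asymptote where the CDF difference underflows.
* The test suite exercises cohorts of 400 (module tests) and 1000
  (acceptance checks) children and a 1000-point EER oracle comparison;
  these sizes give sub-10-second suites while leaving Monte-Carlo noise
  well inside the 3-standard-error contract.

## Known limitations

* The packaged LMS table and CORE points are synthetic/placeholder; both
  are data files the user replaces for clinical use.
* Weight-for-length standards for under-2s are not implemented; the
  under-2 pathways are limited accordingly.
* Recommendation wording and literal weekly menus are configuration
  (tags and templates), not package content.
* The AMDR bounds applied are the 4–18-year ranges for all planned
  children.
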