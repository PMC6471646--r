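# peddst

A computerised decision-support tool (DST) for paediatric healthcare
professionals working on childhood overweight and obesity prevention and
treatment. Given a child's visit record (anthropometry, activity,
clinical flags), the parents' anthropometry and an optional perinatal
history, the package:

1. assesses current weight status from BMI-for-age — BMI by Quetelet's
   equation, $z = ((\mathrm{BMI}/M)^L - 1)/(LS)$ against an LMS growth
   reference, percentile $\Phi(z)\cdot 100$, categories at the 5th/85th/95th
   percentile cutoffs;
2. scores the CORE (Childhood Obesity Risk Evaluation) index for
   normal-weight children, flagging a higher likelihood of future obesity
   at a score $\ge 4$ (point table is runtime configuration);
3. selects the weight-management goal (maintenance vs mild loss) and
   computes the IOM estimated energy requirement, e.g. for boys 9–18 y
   $\mathrm{EER} = 88.5 - 61.9\,a + \mathrm{PA}\,(26.7\,w + 903\,h) + 25$
   kcal/day, then macronutrient targets inside the AMDRs with 4/9/4
   Atwater factors and an exchange-based meal plan scaled to the target;
4. routes the child through the fully enumerated five-step decision tree
   to a recommendation level (R1–R4 or refer), meal plan (MP1–MP4),
   target population (child vs family), goal and re-evaluation interval;
5. renders a deterministic clinician-facing report (JSON or Markdown)
   with items (a)–(f) and a provenance block.

A seeded synthetic-cohort generator emulating the evaluation trial's
baseline population, and the trial's change-score arithmetic, support
end-to-end testing without any external data.

The packaged LMS table is **synthetic** (documented as such) and the CORE
point table is a placeholder; both are plain-text config files you
replace with real reference data for clinical use.

## Worked example

```r
library(peddst)

cfg <- dst_config()  # packaged LMS reference, CORE table, meal plans
fam <- load_records(system.file("extdata", "example_family.json",
                                package = "peddst"))$families[[1]]
a <- assess_family(fam, cfg)
a
#> BMI 25.59 kg/m2 | z = +2.63 | percentile 99.6 | obese
#> R3 | plan MP4 | target child | goal mild_loss | review 3 months
```

The demo child (10 y, 51.9 kg, 142.4 cm, dyslipidaemia flagged,
non-obese parents) is obese for age (99.6th percentile), so the tool
proposes recommendation 3 — child-targeted advice with the
dietary-composition goals — plus hypocaloric meal plan 4 and a 3-month
re-evaluation. The report carries the numbers behind that decision:

```r
cat(render(a$report, "markdown"))
#> ## (c) Energy requirement
#> EER 2519 kcal/day; mild_loss target 2141 kcal/day.
#> ## (d) Macronutrient needs
#> - carb: 52.0% of energy, 278.3 g/day
#> - fat: 30.0% of energy, 71.4 g/day
#> - protein: 18.0% of energy, 96.3 g/day
#> ...
```

Lower-level pieces are exported individually: `assess_weight_status()`,
`score_core()`, `estimate_eer()`, `apply_goal()`,
`macronutrient_targets()`, `scale_meal_plan()`, `decide()`,
`reevaluate()`, `decision_table()` (the complete 80-state mapping),
`generate_cohort()`, `change_score()`, `attrition()`.

A thin command-line wrapper ships at `inst/cli/dst.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","dst.R",package="peddst"))')" \
    report --family family.json --out report.md
```

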