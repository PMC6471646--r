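# Estimated-energy-requirement coefficient sets.
# Provenance: Institute of Medicine, Dietary Reference Intakes for Energy,
# Carbohydrate, Fiber, Fat, Fatty Acids, Cholesterol, Protein, and Amino
# Acids (2005): EER equations for infants (0-35 months), children (3-8 y)
# and adolescents (9-18 y). Heights in metres, weights in kg, ages in years
# (months for the infant bands). Growth energy = energy deposition.
version: "IOM-DRI-2005"
infant_tee:            # total energy expenditure, kcal/day = 89*weight - 100
  weight_coef: 89
  intercept: -100
infant_bands:          # energy deposition by age, kcal/day
  - {max_months: 3, growth_kcal: 175}
  - {max_months: 6, growth_kcal: 56}
  - {max_months: 12, growth_kcal: 22}
  - {max_months: 36, growth_kcal: 20}
child_bands:
  male:
    - {min_years: 3, max_years: 9, intercept: 88.5, age_coef: -61.9,
       weight_coef: 26.7, height_coef: 903, growth_kcal: 20}
    - {min_years: 9, max_years: 19, intercept: 88.5, age_coef: -61.9,
       weight_coef: 26.7, height_coef: 903, growth_kcal: 25}
  female:
    - {min_years: 3, max_years: 9, intercept: 135.3, age_coef: -30.8,
       weight_coef: 10.0, height_coef: 934, growth_kcal: 20}
    - {min_years: 9, max_years: 19, intercept: 135.3, age_coef: -30.8,
       weight_coef: 10.0, height_coef: 934, growth_kcal: 25}
pa_coefficients:       # IOM physical-activity coefficients, 3-18 y
  male: {sedentary: 1.00, low_active: 1.13, active: 1.26, very_active: 1.42}
  female: {sedentary: 1.00, low_active: 1.16, active: 1.31, very_active: 1.56}
# Bridge from the MET-based clinical categories (light < 4 METs,
# moderate 4-7 METs, vigorous > 7 METs) to IOM PA levels. Configuration,
# not a published mapping.
met_category_map:
  light: sedentary
  moderate: low_active
  vigorous: active
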