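# Meal plan 1: isocaloric standard plan (weight maintenance),
# overweight children without clinical disorders.
# reference_energy equals the kcal delivered by the listed exchange counts
# under the packaged exchange composition (4/9/4 Atwater).
id: MP1
goal: maintenance
reference_energy: 1857.5
granularity: 0.5
exchanges:
  starch: 8
  fruit: 3
  vegetable: 4
  milk: 2.5
  meat: 5
  fat: 4
  sweets: 1
constraints:
  max_sucrose_pct_kcal: 12
  min_fibre_g_per_1000kcal: 10
  max_sodium_mg_per_1000kcal: 1500
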