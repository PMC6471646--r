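# Meal plan 3: hypocaloric standard plan (mild weight loss),
# obese 6-15-year-olds without clinical disorders.
id: MP3
goal: mild_loss
reference_energy: 1485
granularity: 0.5
exchanges:
  starch: 6
  fruit: 3
  vegetable: 4
  milk: 2
  meat: 4
  fat: 3
  sweets: 0.5
constraints:
  max_sucrose_pct_kcal: 12
  min_fibre_g_per_1000kcal: 10
  max_sodium_mg_per_1000kcal: 1500
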