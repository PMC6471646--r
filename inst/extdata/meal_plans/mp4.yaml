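# Meal plan 4: hypocaloric plan rich in dietary fibre and complex
# carbohydrates with lower simple sugars, total/saturated fat, cholesterol
# and sodium; obese 6-15-year-olds with at least one clinical disorder.
id: MP4
goal: mild_loss
reference_energy: 1543
granularity: 0.5
exchanges:
  starch: 6
  fruit: 4
  vegetable: 5
  milk: 2
  meat: 4
  fat: 3
  sweets: 0
constraints:
  max_sucrose_pct_kcal: 8
  min_fibre_g_per_1000kcal: 14
  max_sodium_mg_per_1000kcal: 1100
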