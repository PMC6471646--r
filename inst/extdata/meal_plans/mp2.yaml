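# Meal plan 2: isocaloric plan rich in dietary fibre and complex
# carbohydrates with lower simple sugars, total/saturated fat, cholesterol
# and sodium; overweight children with at least one clinical disorder.
id: MP2
goal: maintenance
reference_energy: 1885.5
granularity: 0.5
exchanges:
  starch: 8
  fruit: 4
  vegetable: 5
  milk: 2.5
  meat: 5
  fat: 4
  sweets: 0
constraints:
  max_sucrose_pct_kcal: 8
  min_fibre_g_per_1000kcal: 14
  max_sodium_mg_per_1000kcal: 1100
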