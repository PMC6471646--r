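variable	group	baseline_mean	followup_mean
fibre_g_day	IG	13.0	17.1
fibre_g_day	CG	11.9	12.0
sucrose_g_day	IG	16.0	11.4
sucrose_g_day	CG	11.9	8.7
body_weight_kg	IG	54.3	55.0
body_weight_kg	CG	48.6	50.0
height_cm	IG	143.5	145.5
height_cm	CG	141.3	142.7
bmi_kg_m2	IG	25.6	25.2
bmi_kg_m2	CG	24.1	24.3
bmi_zscore	IG	2.6	2.5
bmi_zscore	CG	2.8	2.8
waist_cm	IG	81.0	81.6
waist_cm	CG	78.3	80.4
chocolates_portions_day	IG	0.70	0.39
chocolates_portions_day	CG	0.55	0.59
cakes_portions_day	IG	0.18	0.05
cakes_portions_day	CG	0.10	0.06
chips_portions_day	IG	0.14	0.06
chips_portions_day	CG	0.09	0.04
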