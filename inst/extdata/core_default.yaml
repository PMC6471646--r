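# PLACEHOLDER CORE (Childhood Obesity Risk Evaluation) score table.
# The published tool states the index components and the high-risk
# threshold (total score >= 4) but not the point assignments; this default
# provides plausible, documented bins so the scorer is usable out of the
# box. Replace with the published coefficients for clinical use.
# Numeric bins are left-closed, right-open [min, max); omitted bounds are
# infinite. All points are non-negative integers.
threshold: 4
missing_policy: zero_points
components:
  - name: child_sex
    field: child_sex
    type: category
    bins:
      - {value: male, points: 1}
      - {value: female, points: 0}
  - name: maternal_prepregnancy_weight_status
    field: maternal_prepregnancy_bmi
    type: numeric
    bins:
      - {max: 25, points: 0}
      - {min: 25, max: 30, points: 1}
      - {min: 30, points: 2}
  - name: maternal_smoking_pregnancy
    field: maternal_smoking_pregnancy
    type: boolean
    bins:
      - {value: true, points: 1}
      - {value: false, points: 0}
  - name: rapid_infant_weight_gain
    field: weight_gain_0_6mo
    type: numeric
    bins:
      - {max: 4.0, points: 0}
      - {min: 4.0, points: 2}
  - name: maternal_education
    field: maternal_education
    type: numeric
    bins:
      - {max: 9, points: 2}
      - {min: 9, max: 13, points: 1}
      - {min: 13, points: 0}
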