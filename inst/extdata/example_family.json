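{
  "child": {
    "id": "demo01",
    "sex": "male",
    "birth_date": "2008-06-15",
    "exam_date": "2018-05-15",
    "weight_kg": 51.9,
    "height_cm": 142.4,
    "measurement_mode": "standing_height",
    "activity_category": "moderate",
    "waist_cm": 79.9,
    "disorders": {
      "hyperglycaemia": false,
      "insulin_resistance": false,
      "dyslipidaemia": true,
      "hypertension": false
    },
    "perinatal": {
      "birth_weight_kg": 3.2,
      "weight_6mo_kg": 7.4,
      "maternal_smoking_pregnancy": false,
      "maternal_prepregnancy_bmi": 24.9,
      "maternal_education_years": 14
    }
  },
  "mother": {
    "weight_kg": 73.4,
    "height_cm": 164,
    "education_years": 14,
    "source": "measured"
  },
  "father": {
    "weight_kg": 89.6,
    "height_cm": 177,
    "source": "reported"
  }
}
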