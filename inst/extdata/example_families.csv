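child_id,child_sex,birth_date,exam_date,weight_kg,height_cm,measurement_mode,activity_category,waist_cm,hyperglycaemia,insulin_resistance,dyslipidaemia,hypertension,birth_weight_kg,weight_6mo_kg,maternal_smoking_pregnancy,maternal_prepregnancy_bmi,maternal_education_years,mother_weight_kg,mother_height_cm,father_weight_kg,father_height_cm
demo01,male,2008-06-15,2018-05-15,51.9,142.4,standing_height,moderate,79.9,FALSE,FALSE,TRUE,FALSE,3.2,7.4,FALSE,24.9,14,73.4,164,89.6,177
demo02,female,2010-02-01,2018-05-15,34.0,128.5,standing_height,light,68.0,FALSE,FALSE,FALSE,FALSE,3.4,8.0,TRUE,31.2,8,88.0,166,78.0,175
demo03,male,2011-09-20,2018-05-15,22.5,118.0,standing_height,vigorous,55.0,FALSE,FALSE,FALSE,FALSE,3.0,6.4,FALSE,22.0,16,60.0,165,80.0,180
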