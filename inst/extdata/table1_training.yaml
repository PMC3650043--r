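# Baseline cohort spec: training-sample marginals (per-sex means/SDs of the
# continuous covariates, smoking and albuminuria prevalences, sex split).
# Pre-diagnosis event-history prevalences are not part of the baseline table
# and default to 0.
'n': 1000
seed: 1
prop_female: 0.4223651
male:
  mean: {age_at_diagnosis: 55.36, diabetes_duration: 8.92, hba1c: 7.34,
         bmi: 28.84, systolic_bp: 141.47, diastolic_bp: 78.85,
         tc_hdl: 4.23, ldl: 2.86}
  sd: {age_at_diagnosis: 9.28, diabetes_duration: 7.14, hba1c: 1.18,
       bmi: 4.44, systolic_bp: 17.51, diastolic_bp: 9.40,
       tc_hdl: 1.29, ldl: 0.88}
  smoker: 0.1507
  macroalbuminuria: 0.0709
  microalbuminuria: 0.2016
female:
  mean: {age_at_diagnosis: 57.15, diabetes_duration: 9.02, hba1c: 7.37,
         bmi: 29.67, systolic_bp: 143.76, diastolic_bp: 77.11,
         tc_hdl: 3.95, ldl: 3.00}
  sd: {age_at_diagnosis: 9.55, diabetes_duration: 7.17, hba1c: 1.18,
       bmi: 5.55, systolic_bp: 18.66, diastolic_bp: 9.38,
       tc_hdl: 1.25, ldl: 0.93}
  smoker: 0.1411
  macroalbuminuria: 0.0403
  microalbuminuria: 0.1380
history: {ami: 0.0, hf: 0.0, stroke: 0.0, naihd: 0.0}
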