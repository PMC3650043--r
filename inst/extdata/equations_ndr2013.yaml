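version: ndr2013-v1
source: Swedish national diabetes register 2004-2008 follow-up; Weibull proportional
  hazards, PWP gap-time; first events on years since diagnosis, second events on
  years since first event
equations:
  ami_first:
    event: ami
    order: first
    time_scale: since_diagnosis
    constant: -7.8187
    shape: 2.0537
    terms:
    - {covariate: female, coef: -0.2318}
    - {covariate: age_at_diagnosis, coef: 0.0541, center: 56.02}
    - {covariate: hba1c, coef: 0.0829, center: 7.27}
    - {covariate: systolic_bp, coef: 0.0079, center: 140.92}
    - {covariate: ldl, coef: 0.1161, center: 2.77}
    - {covariate: tc_hdl, coef: 0.1712, center: 3.89}
    - {covariate: macroalbuminuria, coef: 0.5719}
    - {covariate: microalbuminuria, coef: 0.2176}
    - {covariate: smoker, coef: 0.4938}
    - {covariate: ami_history, coef: 0.7469}
    - {covariate: hf_post, coef: 0.6151}
    splines: []
    interactions: []
    time_terms: []
  ami_second:
    event: ami
    order: second
    time_scale: since_first_event
    constant: -2.5755
    shape: 0.7916
    terms:
    - {covariate: female, coef: 0.1887}
    - {covariate: age_at_diagnosis, coef: 0.0254, center: 56.64}
    - {covariate: ldl, coef: 0.1745, center: 2.54}
    - {covariate: macroalbuminuria, coef: 0.5478}
    - {covariate: smoker, coef: 0.2987}
    - {covariate: ami_history, coef: 0.7704}
    - {covariate: hf_post, coef: 0.3386}
    - {covariate: duration_first_event, coef: 0.0566, center: 10.0}
    splines: []
    interactions:
    - covariates: [female, ldl]
      coef: -0.2155
    time_terms: []
  hf_first:
    event: hf
    order: first
    time_scale: since_diagnosis
    constant: -5.326
    shape: 2.5986
    terms:
    - {covariate: female, coef: -0.4697}
    - {covariate: age_at_diagnosis, coef: 0.0896, center: null}
    - {covariate: tc_hdl, coef: 0.1146, center: null}
    - {covariate: bmi, coef: 0.0631, center: null}
    - {covariate: macroalbuminuria, coef: 0.7841}
    - {covariate: microalbuminuria, coef: 0.6932}
    - {covariate: smoker, coef: 0.3402}
    - {covariate: hf_history, coef: 1.6988}
    splines:
    - {covariate: hba1c, knot: 7.0, coef_low: -0.2424, coef_high: 0.1864, center_low: null,
      center_high: null}
    - {covariate: systolic_bp, knot: 140.0, coef_low: -0.0186, coef_high: 0.005,
      center_low: null, center_high: null}
    interactions: []
    time_terms:
    - {covariate: female, coef: 0.0172, form: linear}
    - {covariate: microalbuminuria, coef: -0.0202, form: linear}
  hf_second:
    event: hf
    order: second
    time_scale: since_first_event
    constant: 0.287
    shape: 0.8149
    terms:
    - {covariate: female, coef: -0.1224}
    - {covariate: age_at_diagnosis, coef: 0.0207, center: null}
    - {covariate: hba1c, coef: 0.0579, center: null}
    - {covariate: smoker, coef: 0.3402}
    - {covariate: duration_first_event, coef: 0.0268, center: null}
    splines: []
    interactions: []
    time_terms:
    - {covariate: null, coef: -1.696, form: step, threshold: 1.0}
    - {covariate: smoker, coef: -0.4124, form: step, threshold: 1.0}
  stroke_first:
    event: stroke
    order: first
    time_scale: since_diagnosis
    constant: -7.1089
    shape: 2.0965
    terms:
    - {covariate: age_at_diagnosis, coef: 0.0727, center: null}
    - {covariate: systolic_bp, coef: 0.0063, center: null}
    - {covariate: diastolic_bp, coef: 0.0113, center: null}
    - {covariate: tc_hdl, coef: 0.1121, center: null}
    - {covariate: macroalbuminuria, coef: 0.397}
    - {covariate: microalbuminuria, coef: 0.2551}
    - {covariate: smoker, coef: 0.401}
    - {covariate: stroke_history, coef: 0.9654}
    - {covariate: hf_post, coef: 0.1826}
    - {covariate: ami_post, coef: 0.3692}
    splines:
    - {covariate: hba1c, knot: 7.0, coef_low: -0.1714, coef_high: 0.1614, center_low: null,
      center_high: null}
    interactions: []
    time_terms: []
  stroke_second:
    event: stroke
    order: second
    time_scale: since_first_event
    constant: -2.4119
    shape: 0.8865
    terms:
    - {covariate: age_at_diagnosis, coef: 0.0288, center: null}
    - {covariate: smoker, coef: 0.8806}
    - {covariate: stroke_history, coef: 0.7675}
    - {covariate: duration_first_event, coef: 0.0518, center: null}
    splines: []
    interactions: []
    time_terms:
    - {covariate: smoker, coef: -0.2326, form: linear}
  naihd_first:
    event: naihd
    order: first
    time_scale: since_diagnosis
    constant: -5.4122
    shape: 1.6704
    terms:
    - {covariate: female, coef: -0.2278}
    - {covariate: age_at_diagnosis, coef: 0.0299, center: null}
    - {covariate: hba1c, coef: 0.058, center: null}
    - {covariate: tc_hdl, coef: 0.1705, center: null}
    - {covariate: bmi, coef: 0.0183, center: null}
    - {covariate: macroalbuminuria, coef: 0.6346}
    - {covariate: microalbuminuria, coef: 0.1937}
    - {covariate: smoker, coef: 0.5724}
    - {covariate: naihd_history, coef: 1.4576}
    splines:
    - {covariate: diastolic_bp, knot: 80.0, coef_low: -0.013, coef_high: 0.0028,
      center_low: null, center_high: null}
    interactions: []
    time_terms:
    - {covariate: smoker, coef: -0.0675, form: linear}
    - {covariate: macroalbuminuria, coef: -0.03, form: linear}
  naihd_second:
    event: naihd
    order: second
    time_scale: since_first_event
    constant: -0.5534
    shape: 0.438
    terms:
    - {covariate: female, coef: 0.0388}
    - {covariate: tc_hdl, coef: 0.0935, center: null}
    - {covariate: macroalbuminuria, coef: -0.3725}
    splines: []
    interactions:
    - covariates: [female, macroalbuminuria]
      coef: 0.599
    time_terms:
    - {covariate: null, coef: -0.3295, form: step, threshold: 3.0}
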