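female,age_at_diagnosis,diabetes_duration,hba1c,systolic_bp,diastolic_bp,ldl,tc_hdl,bmi,smoker,macroalbuminuria,microalbuminuria,ami_history,hf_history,stroke_history,naihd_history,ami_post,hf_post,stroke_post,naihd_post,duration_first_event
0,48,10,8.0,150,80,2.0,4.3,28,0,1,0,0,0,0,0,0,0,0,0,10
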