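"risk_factor","intermediate","unit_value","unit_label","coefficient","se","distribution","note"
"total_fat","cholesterol",1,"%energy",0.02,0.005,"normal",""
"saturated_fat","cholesterol",1,"%energy",0.052,0.003,"normal",""
"mufa","cholesterol",1,"%energy",0.005,0.003,"normal",""
"pufa","cholesterol",1,"%energy",-0.026,0.004,"normal",""
"dietary_cholesterol","cholesterol",1,"g/day",7e-04,1e-04,"normal",""
"salt","sbp",100,"mmol/24h urinary sodium",5.8,1.71,"normal","dietary salt converted to urinary sodium excretion before applying"
"total_energy","bmi",1,"kJ/day",NA,NA,"normal","linear steady-state energy-to-weight coefficient supplied by model configuration"
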