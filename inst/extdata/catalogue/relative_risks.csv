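"risk_factor","disease","unit_value","unit_label","form","sex","band_type","band_low","band_high","value","se","distribution","note"
"fruit","ihd",106,"g/day","rr_per_unit","all","none",NA,NA,0.93,0.019,"lognormal",""
"fruit","stroke",106,"g/day","rr_per_unit","all","none",NA,NA,0.89,0.023,"lognormal",""
"fruit","lung_cancer",100,"g/day","rr_per_unit","all","none",NA,NA,0.94,0.02,"lognormal",""
"vegetables","ihd",106,"g/day","rr_per_unit","all","none",NA,NA,0.89,0.034,"lognormal",""
"vegetables","lung_cancer",100,"g/day","rr_per_unit","all","none",NA,NA,0.94,0.025,"lognormal",""
"fibre_cereal","ihd",10,"g/day","rr_per_unit","all","none",NA,NA,0.91,0.02,"lognormal","cereal fibre only, avoids double counting with fruit and vegetables"
"fibre","breast_cancer",10,"g/day","rr_per_unit","all","none",NA,NA,0.93,0.027,"lognormal",""
"fibre","colorectal_cancer",10,"g/day","rr_per_unit","all","none",NA,NA,0.9,0.034,"lognormal",""
"fibre","stomach_cancer",10,"g/day","rr_per_unit","all","none",NA,NA,0.56,0.12,"lognormal",""
"red_meat","colorectal_cancer",100,"g/day","rr_per_unit","all","none",NA,NA,1.3,0.06,"lognormal",""
"red_meat","stomach_cancer",100,"g/day","rr_per_unit","all","none",NA,NA,1.13,0.036,"lognormal",""
"red_meat","diabetes",100,"g/day","rr_per_unit","all","none",NA,NA,1.2,0.072,"lognormal",""
"processed_meat","colorectal_cancer",50,"g/day","rr_per_unit","all","none",NA,NA,1.38,0.07,"lognormal",""
"processed_meat","diabetes",50,"g/day","rr_per_unit","all","none",NA,NA,1.57,0.1,"lognormal",""
"cholesterol","ihd",-1,"mmol/L","rr_per_unit","all","age",0,49,0.44,0.034,"lognormal",""
"cholesterol","ihd",-1,"mmol/L","rr_per_unit","all","age",50,59,0.58,0.034,"lognormal",""
"cholesterol","ihd",-1,"mmol/L","rr_per_unit","all","age",60,69,0.72,0.018,"lognormal",""
"cholesterol","ihd",-1,"mmol/L","rr_per_unit","all","age",70,79,0.82,0.015,"lognormal",""
"cholesterol","ihd",-1,"mmol/L","rr_per_unit","all","age",80,100,0.85,0.21,"lognormal",""
"cholesterol","stroke",-1,"mmol/L","rr_per_unit","all","age",0,59,0.9,0.037,"lognormal",""
"cholesterol","stroke",-1,"mmol/L","rr_per_unit","all","age",60,69,1.02,0.027,"lognormal",""
"cholesterol","stroke",-1,"mmol/L","rr_per_unit","all","age",70,79,1.04,0.025,"lognormal",""
"cholesterol","stroke",-1,"mmol/L","rr_per_unit","all","age",80,100,1.06,0.031,"lognormal",""
"sbp","ihd",-20,"mmHg","rr_per_unit","all","age",0,49,0.49,0.042,"lognormal",""
"sbp","ihd",-20,"mmHg","rr_per_unit","all","age",50,59,0.5,0.015,"lognormal",""
"sbp","ihd",-20,"mmHg","rr_per_unit","all","age",60,69,0.54,0.0094,"lognormal",""
"sbp","ihd",-20,"mmHg","rr_per_unit","all","age",70,79,0.6,0.013,"lognormal",""
"sbp","ihd",-20,"mmHg","rr_per_unit","all","age",80,100,0.67,0.023,"lognormal",""
"sbp","stroke",-20,"mmHg","rr_per_unit","all","age",0,49,0.36,0.057,"lognormal",""
"sbp","stroke",-20,"mmHg","rr_per_unit","all","age",50,59,0.38,0.034,"lognormal",""
"sbp","stroke",-20,"mmHg","rr_per_unit","all","age",60,69,0.43,0.024,"lognormal",""
"sbp","stroke",-20,"mmHg","rr_per_unit","all","age",70,79,0.5,0.02,"lognormal",""
"sbp","stroke",-20,"mmHg","rr_per_unit","all","age",80,100,0.67,0.03,"lognormal",""
"bmi","ihd",5,"kg/m2","rr_per_unit","all","age",35,59,1.5,0.039,"lognormal",""
"bmi","ihd",5,"kg/m2","rr_per_unit","all","age",60,69,1.4,0.031,"lognormal",""
"bmi","ihd",5,"kg/m2","rr_per_unit","all","age",70,79,1.31,0.033,"lognormal",""
"bmi","ihd",5,"kg/m2","rr_per_unit","all","age",80,89,1.3,0.055,"lognormal",""
"bmi","stroke",5,"kg/m2","rr_per_unit","all","age",35,59,1.76,0.075,"lognormal",""
"bmi","stroke",5,"kg/m2","rr_per_unit","all","age",60,69,1.49,0.056,"lognormal",""
"bmi","stroke",5,"kg/m2","rr_per_unit","all","age",70,79,1.33,0.056,"lognormal",""
"bmi","stroke",5,"kg/m2","rr_per_unit","all","age",80,89,1.1,0.083,"lognormal",""
"bmi","diabetes",5,"kg/m2","rr_per_unit","all","exposure",15,25,0.96,0.25,"lognormal",""
"bmi","diabetes",5,"kg/m2","rr_per_unit","all","exposure",25,50,2.16,0.067,"lognormal",""
"bmi","pancreatic_cancer",5,"kg/m2","rr_per_unit","all","none",NA,NA,1.1,0.016,"lognormal",""
"bmi","colorectal_cancer",5,"kg/m2","rr_per_unit","male","none",NA,NA,1.24,0.016,"lognormal",""
"bmi","colorectal_cancer",5,"kg/m2","rr_per_unit","female","none",NA,NA,1.09,0.019,"lognormal",""
"bmi","breast_cancer",5,"kg/m2","rr_per_unit","female","age",60,100,1.12,0.018,"lognormal",""
"bmi","kidney_cancer",5,"kg/m2","rr_per_unit","male","none",NA,NA,1.24,0.039,"lognormal",""
"bmi","kidney_cancer",5,"kg/m2","rr_per_unit","female","none",NA,NA,1.34,0.034,"lognormal",""
"bmi","liver_cancer",5,"kg/m2","rr_per_unit","all","none",NA,NA,1.47,0.078,"lognormal",""
"bmi","liver_cirrhosis",5,"kg/m2","rr_per_unit","all","exposure",15,25,0.73,0.016,"lognormal",""
"bmi","liver_cirrhosis",5,"kg/m2","rr_per_unit","all","exposure",25,50,1.79,0.077,"lognormal",""
"diabetes","ihd",1,"status","rr_status","male","none",NA,NA,1.85,0.063,"lognormal","relative risk if diabetic vs not"
"diabetes","ihd",1,"status","rr_status","female","none",NA,NA,2.63,0.076,"lognormal","relative risk if diabetic vs not"
"diabetes","stroke",1,"status","rr_status","male","none",NA,NA,1.83,0.067,"lognormal","relative risk if diabetic vs not"
"diabetes","stroke",1,"status","rr_status","female","none",NA,NA,2.28,0.085,"lognormal","relative risk if diabetic vs not"
"physical_activity","ihd",11.25,"METhr/wk","beta_quarter_power","all","none",NA,NA,-0.204,0.027,"normal","beta of quarter-power dose transform, unadjusted for BMI"
"physical_activity","stroke",11.25,"METhr/wk","beta_quarter_power","all","none",NA,NA,-0.195,0.041,"normal","beta of quarter-power dose transform, unadjusted for BMI"
"physical_activity","diabetes",11.25,"METhr/wk","beta_quarter_power","all","none",NA,NA,-0.24,0.023,"normal","beta of quarter-power dose transform, unadjusted for BMI"
"physical_activity","colorectal_cancer",11.25,"METhr/wk","beta_quarter_power","all","none",NA,NA,-0.08,0.059,"normal","beta of quarter-power dose transform, unadjusted for BMI"
"physical_activity","breast_cancer",11.25,"METhr/wk","beta_quarter_power","all","none",NA,NA,-0.053,0.023,"normal","beta of quarter-power dose transform, unadjusted for BMI"
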