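"disease","programme_budget_category","programme_budgeting","specialised_services","primary_care","total_printed","cost_per_prevalent_case","note"
"ihd","10a Coronary Heart Disease",953743,41818,485056,1480617,1905,""
"stroke","10b Cerebrovascular disease",689876,55443,29475,774794,843,""
"diabetes","04a Diabetes",1071537,25577,959716,2056831,444,""
"breast_cancer","02f Cancer breast",472192,0,0,472192,573,"costed directly from a cohort study; specialised and primary care components not applicable"
"colorectal_cancer","02c Cancer lower GI",248315,84919,20,333253,810,"printed total differs from component sum by source rounding"
"lung_cancer","02d Cancer lung",98250,33599,0,131849,904,""
"stomach_cancer","02b Cancer upper GI",32794,11215,0,44008,535,"printed total differs from component sum by source rounding"
"liver_cancer","02b Cancer upper GI",16990,5810,0,22801,1532,"printed total differs from component sum by source rounding"
"kidney_cancer","02h Cancer urological",25145,8599,7833,41577,618,""
"pancreatic_cancer","02b Cancer upper GI",42133,14409,0,56542,3074,""
"liver_cirrhosis","13c Hepatobiliary",59702,4543,2963,67209,314,"printed total differs from component sum by source rounding"
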