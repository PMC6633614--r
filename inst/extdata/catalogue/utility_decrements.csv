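"disease","phase","value","se","distribution"
"ihd","incident",-0.071,0.024,"normal"
"ihd","prevalent",-0.07,0.015,"normal"
"stroke","incident",-0.094,0.019,"normal"
"stroke","prevalent",-0.046,0.031,"normal"
"diabetes","all",-0.071,0.005,"normal"
"breast_cancer","all",-0.019,0.014,"normal"
"colorectal_cancer","all",-0.067,0.017,"normal"
"lung_cancer","all",-0.119,0.043,"normal"
"stomach_cancer","all",-0.071,0.105,"normal"
"liver_cancer","all",-0.093,0.044,"normal"
"kidney_cancer","all",-0.048,0.041,"normal"
"pancreatic_cancer","all",-0.086,0.027,"normal"
"liver_cirrhosis","all",-0.083,0.031,"normal"
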