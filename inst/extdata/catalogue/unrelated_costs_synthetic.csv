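"age","sex","annual_cost"
0,"male",290
1,"male",291.84
2,"male",293.77
3,"male",295.78
4,"male",297.89
5,"male",300.09
6,"male",302.4
7,"male",304.81
8,"male",307.33
9,"male",309.97
10,"male",312.73
11,"male",315.62
12,"male",318.64
13,"male",321.8
14,"male",325.1
15,"male",328.56
16,"male",332.18
17,"male",335.96
18,"male",339.92
19,"male",344.05
20,"male",348.38
21,"male",352.91
22,"male",357.65
23,"male",362.6
24,"male",367.79
25,"male",373.21
26,"male",378.88
27,"male",384.81
28,"male",391.02
29,"male",397.51
30,"male",404.3
31,"male",411.4
32,"male",418.83
33,"male",426.6
34,"male",434.73
35,"male",443.23
36,"male",452.12
37,"male",461.43
38,"male",471.16
39,"male",481.34
40,"male",491.99
41,"male",503.12
42,"male",514.77
43,"male",526.96
44,"male",539.71
45,"male",553.04
46,"male",566.99
47,"male",581.58
48,"male",596.85
49,"male",612.81
50,"male",629.51
51,"male",646.98
52,"male",665.25
53,"male",684.36
54,"male",704.36
55,"male",725.27
56,"male",747.14
57,"male",770.03
58,"male",793.96
59,"male",819
60,"male",845.19
61,"male",872.58
62,"male",901.24
63,"male",931.22
64,"male",962.57
65,"male",995.37
66,"male",1029.68
67,"male",1065.56
68,"male",1103.1
69,"male",1142.37
70,"male",1183.44
71,"male",1226.41
72,"male",1271.35
73,"male",1318.36
74,"male",1367.53
75,"male",1418.97
76,"male",1472.78
77,"male",1529.06
78,"male",1587.93
79,"male",1649.51
80,"male",1713.93
81,"male",1781.31
82,"male",1851.79
83,"male",1925.52
84,"male",2002.64
85,"male",2083.31
86,"male",2167.7
87,"male",2255.96
88,"male",2348.29
89,"male",2444.87
90,"male",2545.9
91,"male",2651.57
92,"male",2762.11
93,"male",2877.74
94,"male",2998.69
95,"male",3125.21
96,"male",3257.55
97,"male",3395.98
98,"male",3540.78
99,"male",3692.25
100,"male",3850.69
0,"female",304.5
1,"female",306.43
2,"female",308.46
3,"female",310.57
4,"female",312.78
5,"female",315.1
6,"female",317.52
7,"female",320.05
8,"female",322.7
9,"female",325.47
10,"female",328.37
11,"female",331.4
12,"female",334.57
13,"female",337.89
14,"female",341.36
15,"female",344.99
16,"female",348.79
17,"female",352.76
18,"female",356.91
19,"female",361.26
20,"female",365.8
21,"female",370.56
22,"female",375.53
23,"female",380.73
24,"female",386.18
25,"female",391.87
26,"female",397.82
27,"female",404.05
28,"female",410.57
29,"female",417.38
30,"female",424.51
31,"female",431.97
32,"female",439.77
33,"female",447.93
34,"female",456.46
35,"female",465.39
36,"female",474.73
37,"female",484.5
38,"female",494.72
39,"female",505.4
40,"female",516.59
41,"female",528.28
42,"female",540.51
43,"female",553.31
44,"female",566.7
45,"female",580.7
46,"female",595.34
47,"female",610.66
48,"female",626.69
49,"female",643.45
50,"female",660.98
51,"female",679.33
52,"female",698.51
53,"female",718.58
54,"female",739.57
55,"female",761.53
56,"female",784.5
57,"female",808.53
58,"female",833.66
59,"female",859.95
60,"female",887.45
61,"female",916.21
62,"female",946.3
63,"female",977.78
64,"female",1010.7
65,"female",1045.14
66,"female",1081.16
67,"female",1118.84
68,"female",1158.26
69,"female",1199.49
70,"female",1242.61
71,"female",1287.73
72,"female",1334.92
73,"female",1384.28
74,"female",1435.91
75,"female",1489.92
76,"female",1546.42
77,"female",1605.51
78,"female",1667.33
79,"female",1731.99
80,"female",1799.63
81,"female",1870.38
82,"female",1944.38
83,"female",2021.8
84,"female",2102.77
85,"female",2187.48
86,"female",2276.08
87,"female",2368.76
88,"female",2465.71
89,"female",2567.12
90,"female",2673.19
91,"female",2784.15
92,"female",2900.22
93,"female",3021.63
94,"female",3148.62
95,"female",3281.47
96,"female",3420.42
97,"female",3565.77
98,"female",3717.82
99,"female",3876.86
100,"female",4043.22
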