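# provenance: synthetic sex-combined 2016 US period life table (smoothed reconstruction)
age,q
0,0.005950000
1,0.000420000
2,0.000317407
3,0.000239875
4,0.000181281
5,0.000137000
6,0.000128382
7,0.000120306
8,0.000112738
9,0.000105646
10,0.000099000
11,0.000121795
12,0.000149838
13,0.000184339
14,0.000226783
15,0.000279000
16,0.000340915
17,0.000416570
18,0.000509014
19,0.000621973
20,0.000760000
21,0.000793848
22,0.000829203
23,0.000866133
24,0.000904707
25,0.000945000
26,0.000986240
27,0.001029280
28,0.001074200
29,0.001121080
30,0.001170000
31,0.001212760
32,0.001257080
33,0.001303020
34,0.001350640
35,0.001400000
36,0.001468880
37,0.001541150
38,0.001616970
39,0.001696530
40,0.001780000
41,0.001934680
42,0.002102800
43,0.002285530
44,0.002484130
45,0.002700000
46,0.002917880
47,0.003153340
48,0.003407810
49,0.003682810
50,0.003980000
51,0.004330560
52,0.004712000
53,0.005127040
54,0.005578630
55,0.006070000
56,0.006557240
57,0.007083600
58,0.007652200
59,0.008266450
60,0.008930000
61,0.009638350
62,0.010402900
63,0.011228100
64,0.012118700
65,0.013080000
66,0.014209400
67,0.015436300
68,0.016769100
69,0.018217100
70,0.019790000
71,0.021589600
72,0.023552800
73,0.025694500
74,0.028031000
75,0.030580000
76,0.033737200
77,0.037220400
78,0.041063200
79,0.045302700
80,0.049980000
81,0.055518700
82,0.061671200
83,0.068505400
84,0.076097100
85,0.084530000
86,0.094459000
87,0.105554000
88,0.117953000
89,0.131808000
90,0.147290000
91,0.162026000
92,0.178235000
93,0.196067000
94,0.215682000
95,0.237260000
96,0.257031000
97,0.278449000
98,0.301652000
99,0.326789000
100,0.354020000
101,0.374664000
102,0.396512000
103,0.419633000
104,0.444103000
105,0.470000000
106,0.488487000
107,0.507702000
108,0.527672000
109,0.548428000
110,0.570000000
111,0.586960000
112,0.604425000
113,0.622410000
114,0.640929000
115,0.660000000
116,0.676844000
117,0.694118000
118,0.711833000
119,0.730000000
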