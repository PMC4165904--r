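age,q_annual
0,0.0019
1,0.00025
2,0.00018803
3,0.00014142
4,0.00010637
5,8e-05
6,7.7892e-05
7,7.5839e-05
8,7.3841e-05
9,7.1895e-05
10,7e-05
11,8.0409e-05
12,9.2366e-05
13,0.0001061
14,0.00012188
15,0.00014
16,0.00015325
17,0.00016774
18,0.00018361
19,0.00020099
20,0.00022
21,0.00022386
22,0.00022779
23,0.00023179
24,0.00023586
25,0.00024
26,0.00024751
27,0.00025526
28,0.00026326
29,0.0002715
30,0.00028
31,0.00029763
32,0.00031638
33,0.00033631
34,0.00035749
35,0.00038
36,0.00041064
37,0.00044376
38,0.00047954
39,0.00051821
40,0.00056
41,0.00061158
42,0.00066791
43,0.00072944
44,0.00079662
45,0.00087
46,0.00095271
47,0.0010433
48,0.0011425
49,0.0012511
50,0.00137
51,0.0014893
52,0.001619
53,0.0017601
54,0.0019134
55,0.00208
56,0.0022643
57,0.002465
58,0.0026834
59,0.0029212
60,0.00318
61,0.0035033
62,0.0038594
63,0.0042517
64,0.0046839
65,0.00516
66,0.0057335
67,0.0063708
68,0.0070789
69,0.0078657
70,0.00874
71,0.0098112
72,0.011014
73,0.012364
74,0.013879
75,0.01558
76,0.017702
77,0.020113
78,0.022852
79,0.025964
80,0.0295
81,0.033771
82,0.03866
83,0.044257
84,0.050665
85,0.058
86,0.065921
87,0.074923
88,0.085154
89,0.096783
90,0.11
91,0.12334
92,0.13831
93,0.15509
94,0.1739
95,0.195
96,0.21394
97,0.23473
98,0.25753
99,0.28255
100,0.31
101,0.33249
102,0.35661
103,0.38249
104,0.41024
105,0.44
106,0.46338
107,0.488
108,0.51393
109,0.54124
110,0.57
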