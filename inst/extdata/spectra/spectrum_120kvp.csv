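energy_keV,relative_fluence
10,2.65799e-09
11,1.41255e-07
12,2.25272e-06
13,1.64617e-05
14,7.12216e-05
15,0.000214405
16,0.00049505
17,0.000950913
18,0.00159349
19,0.00240891
20,0.00336517
21,0.00435663
22,0.00539729
23,0.00645458
24,0.00750143
25,0.00851666
26,0.00948478
27,0.0103952
28,0.0112414
29,0.01202
30,0.01273
31,0.0132685
32,0.013753
33,0.0141861
34,0.0145706
35,0.0149092
36,0.015205
37,0.0154607
38,0.0156791
39,0.0158629
40,0.0160145
41,0.0160786
42,0.0161218
43,0.0161456
44,0.0161513
45,0.0161401
46,0.0161132
47,0.0160717
48,0.0160166
49,0.0159488
50,0.015869
51,0.0157503
52,0.0156239
53,0.0154904
54,0.0153501
55,0.0152035
56,0.0150508
57,0.0148924
58,0.0147287
59,0.0145599
60,0.0143862
61,0.0141909
62,0.0139928
63,0.0137919
64,0.0135883
65,0.0133823
66,0.0131739
67,0.0129632
68,0.0127504
69,0.0125354
70,0.0123184
71,0.0120995
72,0.0118787
73,0.0116562
74,0.011432
75,0.0112061
76,0.0109786
77,0.0107496
78,0.0105192
79,0.0102874
80,0.0100542
81,0.00981431
82,0.00957365
83,0.0093322
84,0.00908998
85,0.00884702
86,0.00860332
87,0.00835893
88,0.00811385
89,0.00786811
90,0.00762172
91,0.00737471
92,0.00712708
93,0.00687887
94,0.00663007
95,0.00638072
96,0.00613082
97,0.00588038
98,0.00562943
99,0.00537798
100,0.00512603
101,0.0048724
102,0.00461846
103,0.00436421
104,0.00410965
105,0.00385479
106,0.00359964
107,0.00334421
108,0.00308849
109,0.00283251
110,0.00257625
111,0.00231973
112,0.00206295
113,0.00180591
114,0.00154863
115,0.00129111
116,0.00103335
117,0.000775351
118,0.000517125
119,0.000258673
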