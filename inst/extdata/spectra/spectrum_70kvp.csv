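energy_keV,relative_fluence
10,7.12032e-09
11,3.75505e-07
12,5.94153e-06
13,4.30678e-05
14,0.000184791
15,0.000551564
16,0.0012624
17,0.00240307
18,0.0039897
19,0.00597388
20,0.00826349
21,0.0105901
22,0.0129831
23,0.0153596
24,0.017653
25,0.0198128
26,0.0218041
27,0.0236051
28,0.0252039
29,0.026597
30,0.0277864
31,0.028555
32,0.0291666
33,0.0296301
34,0.0299549
35,0.0301502
36,0.0302254
37,0.0301892
38,0.03005
39,0.0298158
40,0.0294939
41,0.0289872
42,0.0284226
43,0.0278044
44,0.0271364
45,0.0264224
46,0.0256655
47,0.0248688
48,0.0240352
49,0.0231673
50,0.0222673
51,0.0213
52,0.0203115
53,0.019303
54,0.0182757
55,0.0172309
56,0.0161694
57,0.0150923
58,0.0140004
59,0.0128946
60,0.0117756
61,0.0106313
62,0.00947878
63,0.00831826
64,0.00715017
65,0.00597483
66,0.00479257
67,0.00360368
68,0.00240844
69,0.00120713
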