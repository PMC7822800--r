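energy_keV,relative_fluence
10,4.33596e-09
11,2.29635e-07
12,3.64933e-06
13,2.65715e-05
14,0.000114539
15,0.000343512
16,0.0007901
17,0.00151168
18,0.002523
19,0.00379833
20,0.00528372
21,0.00681082
22,0.00840026
23,0.0100001
24,0.0115678
25,0.0130705
26,0.0144848
27,0.0157952
28,0.0169925
29,0.0180728
30,0.0190358
31,0.0197296
32,0.0203319
33,0.0208475
34,0.0212814
35,0.0216388
36,0.0219247
37,0.0221443
38,0.0223021
39,0.0224028
40,0.0224506
41,0.0223693
42,0.0222533
43,0.0221052
44,0.0219273
45,0.0217216
46,0.0214901
47,0.0212346
48,0.0209567
49,0.0206579
50,0.0203398
51,0.0199682
52,0.0195839
53,0.0191878
54,0.0187804
55,0.0183625
56,0.0179346
57,0.0174974
58,0.0170513
59,0.0165968
60,0.0161344
61,0.0156456
62,0.0151519
63,0.0146537
64,0.014151
65,0.0136441
66,0.0131331
67,0.0126183
68,0.0120997
69,0.0115777
70,0.0110522
71,0.0105235
72,0.00999162
73,0.00945677
74,0.00891902
75,0.00837851
76,0.00783533
77,0.00728959
78,0.00674138
79,0.0061908
80,0.00563793
81,0.0050801
82,0.00452083
83,0.00396018
84,0.00339818
85,0.00283487
86,0.00227029
87,0.00170448
88,0.00113747
89,0.000569302
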