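energy_keV,mu_rho,muen_rho,f_photo,f_compton,f_rayleigh
5,181.875,174,0.994518,0.001131,0.004351
6,105.225,100.475,0.991804,0.001948,0.006248
8,44.4325,42.285,0.984396,0.004579,0.011025
10,22.72425,21.341,0.974067,0.008887,0.017046
15,7.19725,6.64,0.935605,0.027556,0.036839
20,3.2059,2.8417,0.877773,0.060783,0.061444
30,1.09285,0.84275,0.714994,0.172395,0.112612
40,0.56625,0.356,0.529474,0.322273,0.148253
50,0.3747,0.1860725,0.366941,0.472522,0.160537
60,0.2873,0.113145,0.246115,0.598832,0.155053
80,0.21275,0.0582575,0.110059,0.766675,0.123266
100,0.18145,0.0407475,0.05226,0.856286,0.091454
150,0.1483,0.030735,0.011503,0.943205,0.045292
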