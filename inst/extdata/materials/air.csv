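energy_keV,mu_rho,muen_rho,f_photo,f_compton,f_rayleigh
5,40.27,38.8,0.98345,0.004871,0.011678
6,23.41,22.4,0.97498,0.008348,0.016672
8,9.921,9.446,0.951522,0.019552,0.028926
10,5.12,4.742,0.918753,0.037606,0.043641
15,1.614,1.334,0.797605,0.117151,0.085244
20,0.7779,0.5389,0.639642,0.238826,0.121532
30,0.3538,0.1537,0.344874,0.507693,0.147433
40,0.2485,0.06833,0.170378,0.700134,0.129488
50,0.208,0.04098,0.086147,0.811554,0.102299
60,0.1875,0.03041,0.046195,0.874811,0.078994
80,0.1662,0.02407,0.015922,0.935674,0.048404
100,0.1541,0.02325,0.006735,0.961276,0.031989
150,0.1356,0.02496,0.001414,0.983474,0.015112
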