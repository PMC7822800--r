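energy_keV,mu_rho,muen_rho,f_photo,f_compton,f_rayleigh
5,193.4,184,0.992816,0.000979,0.006205
6,115.3,110,0.989459,0.001636,0.008905
8,50.33,48.7,0.980591,0.00372,0.015689
10,26.23,25.43,0.968698,0.007085,0.024217
15,7.955,7.487,0.925027,0.02294,0.052033
20,3.441,3.094,0.861719,0.052109,0.086172
30,1.128,0.8778,0.690866,0.153689,0.155445
40,0.5685,0.3601,0.503306,0.295372,0.201322
50,0.3681,0.184,0.343018,0.442596,0.214386
60,0.2778,0.1099,0.226384,0.56987,0.203746
80,0.2018,0.05511,0.098558,0.74375,0.157693
100,0.1704,0.03794,0.045994,0.839022,0.114984
150,0.1378,0.02827,0.009956,0.93404,0.056004
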