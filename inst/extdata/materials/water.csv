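energy_keV,mu_rho,muen_rho,f_photo,f_compton,f_rayleigh
5,42,40.7,0.983131,0.005194,0.011675
6,24.05,23.1,0.974303,0.009036,0.016661
8,10.37,9.915,0.950311,0.0208,0.028889
10,5.329,4.944,0.916299,0.040177,0.043524
15,1.673,1.374,0.789904,0.125676,0.084421
20,0.8096,0.5503,0.625907,0.255171,0.118922
30,0.3756,0.1557,0.328002,0.531778,0.140221
40,0.2683,0.06947,0.158477,0.72108,0.120443
50,0.2269,0.04223,0.078966,0.827261,0.093772
60,0.2059,0.0319,0.042125,0.885841,0.072034
80,0.1837,0.02597,0.014522,0.941333,0.044146
100,0.1707,0.02546,0.006092,0.96497,0.028938
150,0.1505,0.02764,0.001255,0.985332,0.013413
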