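energy_keV,mu_rho,muen_rho,f_photo,f_compton,f_rayleigh
5,189.5,181,0.997806,0.000946,0.001247
6,118,113,0.996692,0.001514,0.001794
8,52.55,50,0.993446,0.003375,0.003179
9,278.4,260,0.995334,0.000635,0.004031
10,215.9,148.4,0.994214,0.000815,0.004971
15,74.05,57.88,0.986567,0.002335,0.011099
20,33.79,27.88,0.975464,0.005027,0.019509
30,10.92,9.349,0.942547,0.015039,0.042415
40,4.862,4.163,0.895633,0.032716,0.071651
50,2.613,2.192,0.836389,0.059063,0.104549
60,1.593,1.29,0.767679,0.094139,0.138182
80,0.763,0.5581,0.61641,0.186338,0.197251
100,0.4584,0.2949,0.469703,0.295445,0.234852
150,0.2217,0.1027,0.211786,0.549956,0.238259
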