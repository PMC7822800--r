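energy_keV,mu_rho,muen_rho,f_photo,f_compton,f_rayleigh
5,43.3,41.8,0.98331,0.005013,0.011677
6,24.8,23.8,0.974614,0.00872,0.016666
8,10.58,10.09,0.950808,0.020288,0.028905
10,5.34,4.94,0.916564,0.039899,0.043537
15,1.685,1.389,0.79126,0.124174,0.084566
20,0.8165,0.561,0.628753,0.251784,0.119463
30,0.3765,0.1602,0.3307,0.527926,0.141374
40,0.2672,0.07155,0.158791,0.720527,0.120682
50,0.2251,0.04328,0.077796,0.829821,0.092383
60,0.2038,0.03242,0.040363,0.890616,0.069021
80,0.1814,0.02602,0.012715,0.948631,0.038654
100,0.1685,0.02532,0.004728,0.972814,0.022458
150,0.1485,0.02731,0.000535,0.993745,0.00572
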