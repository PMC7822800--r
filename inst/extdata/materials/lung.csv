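energy_keV,mu_rho,muen_rho,f_photo,f_compton,f_rayleigh
5,43.5,42,0.983354,0.004969,0.011677
6,24.9,23.9,0.974685,0.008647,0.016667
8,10.63,10.14,0.950985,0.020105,0.02891
10,5.367,4.964,0.91692,0.039526,0.043554
15,1.693,1.396,0.792276,0.12305,0.084674
20,0.8206,0.5638,0.630725,0.249437,0.119838
30,0.3784,0.161,0.334155,0.522993,0.142851
40,0.2685,0.0719,0.162544,0.713923,0.123533
50,0.2262,0.04349,0.081281,0.822197,0.096521
60,0.2048,0.03258,0.043389,0.882417,0.074195
80,0.1823,0.02615,0.014889,0.939847,0.045264
100,0.1693,0.02544,0.006259,0.964011,0.02973
150,0.1492,0.02745,0.001302,0.984786,0.013913
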