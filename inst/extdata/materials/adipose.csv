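energy_keV,mu_rho,muen_rho,f_photo,f_compton,f_rayleigh
5,24,23,0.975613,0.009143,0.015244
6,14,13.3,0.962724,0.015615,0.021661
8,6.15,5.78,0.927615,0.035281,0.037105
10,3.27,3,0.879187,0.065864,0.054949
15,1.084,0.822,0.705652,0.195115,0.099232
20,0.5727,0.3343,0.509706,0.362868,0.127426
30,0.3096,0.0965,0.224655,0.648976,0.126369
40,0.2405,0.0505,0.095393,0.809214,0.095393
50,0.2105,0.0345,0.04019,0.897014,0.062796
60,0.1949,0.02838,0.01803,0.941401,0.040569
80,0.1769,0.02502,0.003334,0.983329,0.013337
100,0.1655,0.02538,0,1,0
150,0.1467,0.028,0,1,0
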