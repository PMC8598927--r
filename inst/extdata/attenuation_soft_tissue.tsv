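# Mass attenuation coefficient of soft tissue (ICRU-44 like, with coherent
# scattering), approximate tabulation for beam-filtration calculations.
# density_g_cm3: 1.06
energy_keV	mu_rho_cm2_g
1.0	3071
1.5	1028
2.0	557.0
3.0	192.3
4.0	82.77
5.0	41.88
6.0	24.62
8.0	10.38
10.0	5.367
15.0	1.693
20.0	0.8205
30.0	0.3783
40.0	0.2685
50.0	0.2262
60.0	0.2048
80.0	0.1823
100.0	0.1693
125.0	0.1577
150.0	0.1492
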