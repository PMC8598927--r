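# Mass attenuation coefficient of beryllium (with coherent scattering),
# approximate tabulation for beam-filtration calculations.
# density_g_cm3: 1.848
energy_keV	mu_rho_cm2_g
1.0	604.1
1.5	179.7
2.0	74.69
3.0	21.27
4.0	8.685
5.0	4.369
6.0	2.527
8.0	1.124
10.0	0.6466
15.0	0.3070
20.0	0.2251
30.0	0.1792
40.0	0.1640
50.0	0.1554
60.0	0.1493
80.0	0.1401
100.0	0.1328
125.0	0.1250
150.0	0.1190
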