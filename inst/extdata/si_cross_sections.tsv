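# Partial mass interaction coefficients of silicon (cm^2/g), approximate
# tabulation used to classify primary photon interactions by type.
# Columns: photoelectric absorption, incoherent (Compton) scattering,
# coherent (Rayleigh) scattering.
energy_keV	photoelectric	incoherent	coherent
5.0	244.0	0.070	2.18
8.0	64.7	0.105	1.35
10.0	32.7	0.125	1.00
15.0	9.60	0.150	0.500
20.0	3.94	0.160	0.300
30.0	1.08	0.167	0.145
40.0	0.420	0.168	0.085
50.0	0.200	0.166	0.056
60.0	0.105	0.163	0.040
80.0	0.040	0.154	0.023
100.0	0.019	0.146	0.015
120.0	0.0105	0.138	0.0105
140.0	0.0063	0.132	0.0078
150.0	0.0052	0.129	0.0070
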