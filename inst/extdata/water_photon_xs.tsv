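# Photon interaction data for liquid water (unit density), 10-800 keV.
# photoelectric_cm2_g: photoelectric mass attenuation coefficient, smooth
#   parametrisation anchored at low energy (negligible above ~50 keV where
#   incoherent scattering dominates; incoherent cross sections are computed
#   analytically from the Klein-Nishina formula with Z/A = 0.55509).
# mu_en_cm2_g: mass energy-absorption coefficient, standard compilation
#   values; used by the deterministic first-flight photon absorbed-fraction
#   estimate.  Log-log interpolated between rows.
energy_kev	photoelectric_cm2_g	mu_en_cm2_g
10	4.94	4.944
15	1.376	1.374
20	0.558	0.5503
30	0.1549	0.1557
40	0.0625	0.0695
50	0.0310	0.04223
60	0.01745	0.03190
80	0.00701	0.02597
100	0.00346	0.02546
150	0.000958	0.02764
200	0.000388	0.02967
300	0.000108	0.03192
400	4.4e-05	0.03279
500	2.2e-05	0.03299
600	1.25e-05	0.03284
800	5.0e-06	0.03206
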