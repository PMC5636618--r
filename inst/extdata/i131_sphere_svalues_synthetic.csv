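# Synthetic reference S-values for iodine-131 in unit-density water spheres.
# NOT a published compilation: computed by the package deterministic
# quadrature route (CSDA electron absorbed fractions + first-flight mu_en
# photon absorbed fractions) and frozen here as the validation reference
# for the event-by-event Monte Carlo (10 % agreement criterion).
"mass_g","s_gy_per_bq_s","provenance"
0.1,2.76385e-10,"synthetic: deterministic CSDA + first-flight quadrature (radmibg)"
0.2,1.42683e-10,"synthetic: deterministic CSDA + first-flight quadrature (radmibg)"
0.5,5.90645e-11,"synthetic: deterministic CSDA + first-flight quadrature (radmibg)"
1,3.0187e-11,"synthetic: deterministic CSDA + first-flight quadrature (radmibg)"
2,1.5397e-11,"synthetic: deterministic CSDA + first-flight quadrature (radmibg)"
5,6.31491e-12,"synthetic: deterministic CSDA + first-flight quadrature (radmibg)"
10,3.21866e-12,"synthetic: deterministic CSDA + first-flight quadrature (radmibg)"
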