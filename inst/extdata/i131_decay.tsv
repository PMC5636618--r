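# Iodine-131 decay scheme (daughter Xe-131, Z = 54).
# Transcribed from standard MIRD/ICRP-style nuclear decay compilations.
# Inventory truncation: beta branches with intensity >= 0.1 %, discrete
# photon/electron lines with yield >= 0.5 %; Auger and low-energy conversion
# electrons below 10 keV lumped into one locally-deposited 3.4 keV line.
# Columns:
#   record  half_life | beta | photon | electron
#   energy_kev  beta: endpoint energy; otherwise line energy (NA for half_life)
#   value   half_life: hours; beta: intensity per decay; lines: yield per decay
record	energy_kev	value	note
half_life	NA	192.6048	8.0252 d
beta	247.9	0.0212	to 667 keV level
beta	303.9	0.0062	to 637 keV level
beta	333.8	0.0723	to 364 keV level
beta	606.3	0.8960	to 364 keV level (main branch)
beta	806.9	0.0040	to ground state
photon	80.185	0.0262	gamma
photon	284.305	0.0612	gamma
photon	364.489	0.8150	gamma (principal line)
photon	636.989	0.0716	gamma
photon	722.911	0.0177	gamma
photon	29.458	0.0140	Xe K-alpha2 X-ray
photon	29.779	0.0260	Xe K-alpha1 X-ray
photon	33.624	0.0088	Xe K-beta X-ray
electron	329.93	0.0155	CE-K of 364.5 keV transition
electron	45.62	0.0354	CE-K of 80.2 keV transition
electron	3.43	0.0500	lumped Auger/low-energy CE (deposited locally)
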