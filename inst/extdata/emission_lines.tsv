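# K-alpha emission lines: energies after Bearden; K-shell fluorescence
# yields after Krause (1979); g = Kalpha fraction of K-series emission
# (approximate, standard Kbeta/Kalpha ratios). Generated 2026-10-01.
element	transition	energy_keV	fluor_yield	transition_prob	edge_keV
Si	Ka	1.74	0.05	0.97	1.8389
P	Ka	2.0137	0.063	0.95	2.1455
S	Ka	2.3078	0.078	0.94	2.472
Cl	Ka	2.6224	0.097	0.925	2.8224
K	Ka	3.3138	0.14	0.905	3.6074
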