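# Synthetic site-site parameter table for crystalline benzene (crystalhop).
#
# SYNTHETIC MODEL: this table is NOT a transcription of any published benzene
# potential. It combines Williams-type aromatic exp-6 magnitudes (A in kJ/mol,
# B in 1/Angstrom, C6 in kJ mol^-1 Angstrom^6), Tang-Toennies order-6
# dispersion damping, and a small anisotropic range shift d1 (Angstrom) that
# pulls the carbon repulsive wall inward for approaches along the ring
# normal. Point charges live with the reference geometry (benzene_geometry),
# not in this table. Values chosen once for physical plausibility; see the
# methods vignette.
types C H
damp TRUE
A C C 349908.0
A C H 62351.0
A H H 11104.0
B C C 3.60
B C H 3.67
B H H 3.74
C6 C C 2377.0
C6 C H 569.4
C6 H H 136.4
d1 C -0.05
d1 H 0.0
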