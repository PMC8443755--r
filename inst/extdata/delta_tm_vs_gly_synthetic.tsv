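# SYNTHETIC stand-in table: change in model-peptide melting temperature when
# the guest residue replaces glycine (degrees C, glycine = 0 by definition).
# The published per-residue scale used for the delta_t_d_m feature is in a
# supplementary table that is not bundled here; these placeholder values were
# constructed to track helix-propensity ordering (Pace & Scholtz 1998) and
# MUST be replaced with the exact source table for faithful reuse.
aa	delta_tm
A	4.6
R	2.6
N	0.6
D	1.0
C	1.6
Q	2.8
E	3.2
G	0.0
H	1.4
I	2.2
L	3.8
K	2.4
M	3.4
F	1.8
P	-6.0
S	0.8
T	0.4
W	1.2
Y	0.9
V	1.5
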