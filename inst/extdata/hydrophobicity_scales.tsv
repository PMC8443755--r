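# Sidechain transfer free-energy hydrophobicity scales (kcal/mol).
# kD_cyclohexane_water: Radzicka & Wolfenden (1988) Biochemistry 27:1664,
#   cyclohexane -> water transfer free energy of sidechain analogs.
# kD_vapor_to_water: Wolfenden et al. (1981) Biochemistry 20:849, vapor ->
#   water hydration potentials of sidechain analogs.
# kD_octanol_to_water: Fauchere & Pliska (1983) Eur J Med Chem 18:369,
#   octanol -> water pi values.
# Values transcribed to two decimals. Proline has no sidechain analog in the
# Radzicka/Wolfenden studies and is set to 0.00 there; swap this file for the
# exact supplementary tables if they become available.
aa	kD_cyclohexane_water	kD_vapor_to_water	kD_octanol_to_water
A	1.81	1.94	0.31
R	-14.92	-19.92	-1.01
N	-6.64	-9.68	-0.60
D	-8.72	-10.95	-0.77
C	1.28	-1.24	1.54
Q	-5.54	-9.38	-0.22
E	-6.81	-10.20	-0.64
G	0.94	2.39	0.00
H	-4.66	-10.27	0.13
I	4.92	2.15	1.80
L	4.92	2.28	1.70
K	-5.55	-9.52	-0.99
M	2.35	-1.48	1.23
F	2.98	-0.76	1.79
P	0.00	0.00	0.72
S	-3.40	-5.06	-0.04
T	-2.57	-4.88	0.26
W	2.33	-5.88	2.25
Y	-0.14	-6.11	0.96
V	4.04	1.99	1.22
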