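gene_name	direction	deltaBeta	pvalue
SLC36A3	up	0.58	1.31E-03
REPIN1	down	-0.52	3.87E-04
NINJ2	down	-0.47	5.82E-05
GPR88	down	-0.43	2.86E-04
HLA-DRB1	down	-0.42	6.26E-03
LOC100049716	down	-0.40	1.49E-06
GSTM1	down	-0.38	6.56E-03
ATP5S	down	-0.30	4.24E-06
HS1BP3	up	0.28	3.63E-03
PHGR1	down	-0.24	8.15E-03
NDRG4	down	-0.22	7.90E-04
ADCY9	down	-0.21	5.83E-03
PPFIA4	up	0.21	7.03E-03
FAM45A	down	-0.21	2.32E-03
SLCO3A1	down	-0.21	8.34E-04
GALNT2	down	-0.20	1.27E-05
HLA-DQB2	up	0.20	6.48E-03
PTEN	down	-0.20	2.15E-03
ACSF3	down	-0.19	1.03E-03
FOXN3	up	0.19	8.61E-03
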