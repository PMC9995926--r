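gene_name	direction	log2FoldChange	pvalue	FDR
LPIN1	up	8.26	1.62E-19	4.97E-15
PPP1R16B	down	-7.95	2.36E-07	3.69E-05
PIK3R5	down	-7.87	1.91E-07	3.00E-05
PAPOLG	down	-7.57	3.07E-07	4.75E-05
GIGYF2	down	-7.09	2.55E-25	1.96E-20
YAF2	down	-7.09	8.26E-07	1.24E-04
HYOU1	down	-7.05	7.94E-07	1.19E-04
HSPH1	up	7.01	1.57E-03	9.78E-02
TRERF1	down	-6.99	5.26E-12	1.81E-09
ASB13	up	6.96	4.97E-22	2.54E-17
RAB1A	down	-6.89	2.27E-06	3.32E-04
APLP2	down	-6.59	3.48E-10	5.97E-08
SH3BP4	down	-6.58	2.63E-17	3.10E-13
PLEKHO2	down	-6.55	3.13E-06	4.50E-04
C4orf33	down	-6.41	2.96E-06	4.25E-04
RGPD3	up	6.39	6.28E-18	1.21E-13
DCTD	down	-6.36	1.36E-05	1.81E-03
UBE2D3	down	-6.36	2.06E-16	1.31E-12
SLC25A36	down	-6.35	4.02E-04	3.54E-02
SULF2	down	-6.34	1.99E-16	1.31E-12
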