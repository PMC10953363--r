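protein_id	uniprot_id	M1	M2a	M2c
CR1	P17927	-3.02	0.58	-3.36
ITGAL	P20701	0.66	-0.84	-4.02
ITGAM	P11215	-1.51	0.69	-2.26
CD44	P16070	-1.31	-0.86	-1.78
CD58	P19256	-0.59	-0.73	-1.43
CD63	P08962	1.44	-0.60	1.48
LAMP2	P13473	0.36	-0.64	1.43
SLC2A3	P11169	0.89	-0.61	-1.42
IGF2R	P11717	1.04	-0.48	-0.58
NCSTN	Q92542	-0.46	-0.05	-0.52
GLIPR1	P48060	0.07	1.08	0.08
C5AR1	P21730	-1.83	-2.05	0.79
FCGR2A	P12318	-1.42	-2.99	1.12
NFAM1	Q8NET5	0.22	-1.31	-0.36
PTPRC	P08575	-0.79	-1.35	-0.56
CYBB	P04839	-0.49	-2.16	-0.07
DSC1	Q08554	-0.65	-0.91	1.06
PTPRJ	Q12913	-1.02	-0.34	-0.16
MILR1	Q7Z6M3	-1.37	-0.85	0.50
ADAM10	O14672	-1.13	-0.11	0.80
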