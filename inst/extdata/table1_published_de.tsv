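# Transcription of the published table of genes differentially expressed at
# FDR < 0.1 in HELUs vs paired TDLUs and/or ADH/DCIS vs matched HN tissue.
# ND = confidence bound not determined; NA = no probe set on HG-U133A.
# MME's ADH/DCIS FDR is printed "<0.001" and stored here as 0.001.
gene	category	fc_helu	ci_low_helu	ci_high_helu	fdr_helu	fc_adh_dcis	ci_low_adh_dcis	ci_high_adh_dcis	fdr_adh_dcis
EGF	common	-4.17	ND	ND	0.019	-1.04	-1.71	-0.37	0.034
ELF5	common	-2.46	-3.60	-1.31	0.058	-1.88	-2.75	-1.00	0.005
FOXC1	common	-2.69	-3.63	-1.76	0.023	-0.95	-1.38	-0.51	0.004
JAG2	common	-0.53	-0.82	-0.23	0.078	-0.92	-1.37	-0.48	0.006
SOX10	common	-1.16	-1.69	-0.64	0.058	-1.38	-1.92	-0.85	0.001
ABCG2	helu_exclusive	-2.84	-4.28	-1.39	0.073	-0.62	-1.20	-0.04	0.149
CDC42	helu_exclusive	0.66	0.25	1.07	0.091	0.99	-0.12	0.31	0.914
CLDN10	helu_exclusive	-2.70	-4.52	-1.06	0.091	0.33	-0.26	0.93	0.864
EPCAM	helu_exclusive	0.88	0.60	1.17	0.019	0.14	-0.42	0.69	0.928
EZH1	helu_exclusive	-0.74	-1.12	-0.35	0.073	0.12	-0.35	0.58	0.928
FOXA1	helu_exclusive	2.03	1.05	3.00	0.064	0.48	-0.28	1.25	0.855
HOXB2	helu_exclusive	1.83	1.40	2.26	0.008	-0.07	-0.72	0.58	0.959
HOXC10	helu_exclusive	1.09	ND	ND	0.091	0.22	-0.30	0.74	0.914
HOXC11	helu_exclusive	3.03	1.22	4.84	0.091	0.13	-0.15	0.42	0.913
IL7R	helu_exclusive	-2.33	-3.75	-0.90	0.091	0.23	-0.38	0.84	0.914
ITGA6	helu_exclusive	-0.85	-1.28	-0.41	0.073	-0.27	-1.15	0.60	0.914
ITGB1	helu_exclusive	-0.82	-1.17	-0.48	0.049	0.58	0.12	1.04	0.830
ITGB4	helu_exclusive	-0.81	-1.23	-0.38	0.073	-0.02	-0.34	0.30	0.960
MFGE8	helu_exclusive	-1.19	-1.87	-0.52	0.078	-0.20	-0.60	0.20	0.899
MLL4	helu_exclusive	-0.61	-0.99	-0.22	0.092	0.04	-0.60	0.68	0.960
MYC	helu_exclusive	-2.85	-4.46	-1.24	0.078	-0.45	-1.19	0.28	0.855
NOTCH3	helu_exclusive	-0.49	-0.76	-0.23	0.077	0.04	-0.22	0.30	0.959
PGR	helu_exclusive	2.46	1.49	3.42	0.038	0.13	-1.21	1.46	0.959
PROM1	helu_exclusive	-3.17	-4.98	-1.36	0.078	-0.78	-1.96	0.40	0.849
SMARCA4	helu_exclusive	-0.77	-1.21	-0.34	0.078	0.11	-0.20	0.42	0.914
SOX9	helu_exclusive	-2.45	-3.58	-1.31	0.058	-0.26	-1.01	0.49	0.914
TGFA	helu_exclusive	-1.50	-2.41	-0.58	0.091	-0.08	-0.42	0.25	0.928
TGFB2	helu_exclusive	-1.04	ND	ND	0.092	-0.14	-0.71	0.42	0.928
ACTA2	adh_dcis_exclusive	-0.32	-0.71	0.06	0.353	-2.25	-2.95	-1.55	0.0001
AKT1	adh_dcis_exclusive	0.21	-0.65	1.08	0.798	1.07	0.41	1.72	0.029
CBX8	adh_dcis_exclusive	-0.82	-1.55	-0.08	0.207	-0.97	-1.58	-0.37	0.029
CD24	adh_dcis_exclusive	0.29	-0.89	1.46	0.799	0.65	0.34	0.95	0.006
CLDN7	adh_dcis_exclusive	0.24	ND	ND	0.789	0.49	0.17	0.82	0.036
EGFR	adh_dcis_exclusive	-0.65	-1.20	-0.09	0.184	-0.62	-0.90	-0.34	0.004
EZH2	adh_dcis_exclusive	0.90	-0.31	2.12	0.412	1.61	0.87	2.34	0.004
GATA3	adh_dcis_exclusive	1.12	ND	ND	0.136	0.95	0.47	1.43	0.008
HOXA4	adh_dcis_exclusive	-1.13	-1.92	-0.35	0.123	-0.64	-1.05	-0.22	0.036
HOXA5	adh_dcis_exclusive	-1.40	-2.61	-0.18	0.189	-1.93	-2.50	-1.35	0.0001
HOXA7	adh_dcis_exclusive	-1.54	-2.78	-0.29	0.174	-0.77	-1.14	-0.40	0.006
HOXA9	adh_dcis_exclusive	NA	NA	NA	NA	-3.31	-4.66	-0.96	0.002
HOXB6	adh_dcis_exclusive	0.74	ND	ND	0.685	0.92	0.32	1.52	0.075
ID2	adh_dcis_exclusive	-0.34	-1.31	0.64	0.699	0.59	0.21	0.96	0.063
JAM2	adh_dcis_exclusive	-0.62	-2.06	0.82	0.638	-0.91	-1.32	-0.49	0.004
JAM3	adh_dcis_exclusive	-0.55	-1.58	0.49	0.566	-1.09	-1.50	-0.68	0.001
KRT17	adh_dcis_exclusive	0.06	-0.65	0.77	0.948	-1.63	-2.56	-0.71	0.013
MME	adh_dcis_exclusive	-0.44	-1.35	0.46	0.611	-4.42	-5.58	-3.25	0.001
PDGFA	adh_dcis_exclusive	-0.98	-1.77	-0.18	0.174	-1.28	-1.94	-0.63	0.008
SNAI2	adh_dcis_exclusive	-0.65	-1.58	0.29	0.439	-1.79	-2.59	-0.99	0.004
TGFBR3	adh_dcis_exclusive	-0.85	-1.65	-0.05	0.229	-2.02	-3.09	-0.96	0.010
TJP3	adh_dcis_exclusive	-0.47	-0.99	0.04	0.294	1.13	0.51	1.76	0.013
WNT5B	adh_dcis_exclusive	0.21	-0.86	1.27	0.864	-2.71	-3.75	-1.66	0.001
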