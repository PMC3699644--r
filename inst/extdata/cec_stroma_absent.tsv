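gene_id	cec_young	cec_old	cec_culture	stroma
OLFML1	96.55	69.52	19.64	0.55
CYYR1	94.39	15.68	10.14	0.00
HEMK1	91.52	71.61	41.86	0.55
ACAD8	90.09	26.66	25.90	0.55
ATRN	75.01	58.54	48.34	0.55
GNAZ	70.70	70.56	27.84	0.55
HIPK1	70.70	12.02	17.05	0.00
FBP1	60.66	65.34	31.07	0.55
LARS	59.58	26.66	18.99	0.55
GSTZ1	53.84	47.56	71.64	0.00
NUP54	51.32	10.98	10.57	0.55
UBA5	50.96	35.54	13.38	0.55
UBR7	50.25	35.02	58.70	0.55
KIAA1549	47.02	36.59	12.08	0.55
SRGAP2	46.30	17.25	29.13	0.00
NUAK1	45.22	15.16	26.76	0.55
ZFPL1	43.79	49.13	90.85	0.55
UPRT	43.07	28.23	15.11	0.55
KIF3C	42.71	12.54	11.01	0.55
UPRT	42.35	28.23	15.11	0.55
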