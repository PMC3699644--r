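gene_id	cec_young	cec_old	cec_culture	stroma	fold_young_stroma	fold_young_old
KLF10	566	719	80	195	2.9	0.8
SNURF	539	272	547	235	2.3	2.0
PER1	300	192	57	93	3.2	1.6
ILF2	290	435	379	62	4.7	0.7
MAFF	289	297	36	119	2.4	1.0
PITX2	288	567	377	11	27.3	0.5
TFAP2B	277	244	110	5	45.5	0.9
SF1	184	244	115	32	5.8	0.5
SMAD3	180	275	55	38	4.7	0.7
ERG	127	102	64	24	5.3	1.2
STAT1	125	212	166	57	2.2	0.6
SMYD3	122	109	78	2	55	1.1
TCEB3	118	93	99	6	21.3	1.3
EPAS1	118	156	90	49	2.4	0.8
CAND1	118	183	85	49	2.4	0.6
REPIN1	113	64	103	12	9.7	1.8
NFKBIZ	107	110	17	52	2.0	1.0
KBTBD4	103	64	71	12	8.4	1.6
L3MBTL2	102	71	23	37	2.7	1.4
TCEB2	100	128	95	42	2.4	0.8
POLR3H	95	53	132	35	2.7	1.8
KLF9	89	141	47	19	4.7	0.6
GTF2IRD1	81	51	23	1	72.8	1.6
COPS5	77	88	365	33	2.3	0.9
RXRB	75	93	50	8	9.1	0.8
ZNF3	71	84	26	10	7.1	0.8
ZNF143	67	72	49	31	2.2	0.9
YAP1	66	67	35	6	10.8	1.0
ING1	65	96	25	2	29.4	0.7
ZBTB47	65	36	25	1	58.5	1.8
ZKSCAN5	63	34	22	2	28.5	1.8
FOXC1	60	113	24	9	6.7	0.5
ZNF664	59	50	53	28	2.1	1.2
ZMYM4	58	61	19	2	34.9	1.0
SPRYD4	57	36	47	11	5.1	1.6
TCEAL8	57	54	58	13	4.4	1.0
ZFHX4	56	81	44	2	33.4	0.7
E2F4	55	35	35	27	2.1	1.6
RUVBL2	55	95	153	5	10.9	0.6
LMX1B	54	38	57	2	24.4	1.4
TARDBP	52	34	44	8	6.3	1.5
TBPL1	51	54	18	2	30.6	0.9
GZF1	48	75	60	3	14.3	0.6
ZFPL1	44	49	91	1	78.9	0.9
HCFC2	37	61	16	2	22	0.6
ZMAT3	36	22	33	8	4.6	1.6
PCGF3	35	41	13	4	9.0	0.8
RBX1	34	18	49	14	2.4	1.9
STAT2	33	57	102	8	4.2	0.6
CTBP2	32	39	38	3	11.6	0.8
ZNF862	31	22	11	2	13.7	1.4
QRICH1	30	30	11	1	54.3	1.0
CREM	27	52	56	3	9.7	0.5
EGFL6	23	32	29	1	21	0.7
RNF14	23	25	19	4	6.0	0.9
RBL2	23	38	19	4	6.0	0.6
NFYC	22	33	13	5	4.4	0.7
CREB3L4	20	19	47	1	36.9	1.1
CTBP1	20	10	17	3	6.0	1.9
MAF	20	21	12	6	3.2	0.9
NFYA	19	14	13	1	34.3	1.4
ZNF740	16	25	24	2	7.1	0.6
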