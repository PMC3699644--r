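gene_id	cec_young	cec_old	cec_culture	stroma	fold_young_stroma	fold_young_old
SLC2A1	5598	4593	3491	1921	2.9	1.2
ATP5B	4762	4413	3095	1330	3.6	1.1
ATP1A1	2616	1627	858	368	7.1	1.6
ATP5A1	2586	1737	1640	979	2.6	1.5
SLC4A11	2313	2940	366	90	25.7	0.8
SLC25A4	540	536	396	116	4.7	1.0
ATP6V1E1	402	403	479	188	2.1	1.0
PCOLCE	397	601	317	42	9.4	0.7
ATP5G1	236	279	189	113	2.1	0.8
SLC22A4	231	143	35	5	46.3	1.6
SORT1	216	237	214	8	27.8	0.9
SLC15A4	195	358	104	43	4.6	0.5
SVEP1	182	257	390	11	16.4	0.7
ATP5J	162	141	129	23	6.9	1.2
SLC25A11	132	85	152	23	5.8	1.6
TAP1	128	192	126	6	20.9	0.7
ATP6V0D1	126	113	245	62	2.0	1.1
SLC4A4	113	221	41	29	3.9	0.5
ATP6V1D	109	161	374	43	2.5	0.7
SLC35E1	107	71	63	11	9.6	1.5
PAPPA	79	97	89	4	20.2	0.8
SLC2A3	73	77	18	32	2.3	0.9
LRPPRC	64	54	37	5	12.9	1.2
SLC25A13	59	103	16	12	5.1	0.6
SLC39A6	59	83	27	14	4.1	0.7
TM9SF2	55	30	28	19	2.8	1.8
COX11	55	94	44	24	2.2	0.6
VPS33B	52	63	33	4	13.4	0.8
TM9SF1	51	29	191	4	13.1	1.7
SEC61A2	45	87	15	2	20.1	0.5
SLC5A3	43	40	22	13	3.3	1.1
SLC16A2	38	58	304	11	3.6	0.6
PITPNM1	36	46	33	1	32.7	0.8
ABCF3	36	36	60	14	2.6	1.0
TOM1L2	34	24	26	4	7.7	1.4
SLC26A11	33	28	12	1	30.1	1.2
SLC35B3	29	36	113	2	17.2	0.8
SLC16A3	28	38	86	4	6.3	0.7
SLC4A2	27	51	85	6	4.8	0.5
CACNB3	27	40	41	1	47.9	0.7
AP3D1	24	32	114	3	7.2	0.7
IPO9	22	11	77	6	3.5	1.9
SLC45A1	18	16	13	1	16.5	1.1
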