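gene_id	cec_young	cec_old	cec_culture	stroma	fold_young_old	fold_young_culture	fold_young_stroma	flaw1	flaw2	flaw3	flaw4
AQP1	233	172	4	506	1.35	54.0	0.5		Y	Y	Y
ATP1A1	2,616	1,627	858	368	1.61	3.1	7.1				Y
CLCN2	13	0	1	4	n/a	11.6	2.8	Y	Y	Y	
CLCN3	15	5	79	5	2.82	0.2	3.0	Y		Y	Y
COL8A2	1,821	1,743	859	107	1.04	2.1	17.0				R
ENO2	495	247	57	104	2.0	8.7	4.8			Y	Y
JAM1	0.80	0.50	3.70	86	1.60	0.22	0.01	Y	Y	Y	Y
NCAD	129	67	94	4	1.92	1.4	33.3				Y
PTGDS	5,547	6,415	183	2,522	0.86	30.2	2.2		?	Y	Y
SLC4A11	2,313	2,940	366	90	0.79	6.3	25.7		?		
SLC4A4	113	221	41	29	0.51	2.8	3.9			Y	Y
VDAC2	248	135	134	172	1.83	1.9	1.4			Y	Y
VDAC3	582	393	299	250	1.48	2.0	2.3			Y	
ZO-1	49	42	8	72	1.17	6.3	0.7	Y	Y	Y	Y
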