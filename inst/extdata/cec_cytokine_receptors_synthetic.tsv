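gene_id	cec_young	cec_old	cec_culture	stroma	fold_young_stroma	fold_young_old
TGFBR3	135	130	11	44	3.1	1.0
IL13RA1	78	95	50	16	4.8	0.8
IL6ST	43	76	25	9	4.5	0.6
IFNGR1	120	110	8	30		
IL1R1	250	240	150	200		
TNFRSF1A	400	150	120	100		
IL4R	8	6	20	1		
OSMR	90	30	40	10		
IL10RB	60	55	50	40		
ACVR2A	15	40	12	0		
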