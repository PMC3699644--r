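gene_id	cec_young	cec_old	cec_culture	stroma
SMAD3	180	275	55	38
SMAD2	106	45	82	131
SMAD4	28	11	35	0
SMAD5	23	0	3	2
SMAD9	14	0	0	0
SMAD7	5	46	1	3
SMAD6	1	0	0	0
SMAD1	0	5	0	0
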