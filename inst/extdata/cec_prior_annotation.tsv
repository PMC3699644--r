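gene_id	categories	specificity
AQP1		ubiquitous
ATP1A1		ubiquitous
CLCN2		specific
CLCN3		ubiquitous
COL8A2		restricted:retina
ENO2		ubiquitous
JAM1		ubiquitous
NCAD		ubiquitous
PTGDS		ubiquitous
SLC4A11		specific
SLC4A4		ubiquitous
VDAC2		ubiquitous
VDAC3		specific
ZO-1		ubiquitous
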