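term	percent	genes
Generation of precursor metabolites and energy	28.6	ALDOA,LDHA,ATP5B,ALDOC,PFKP,COX4I1,ATP5G3,TPI1,SLC25A3,GNAS,ATP5A1,PGK1,GAPDH,ENO1
Response to organic substance	18.4	HSP90AB1,FOS,HERPUD1,GLUL,ALDOC,MGP,GNAS,ATP5G3,HSPA8
Glycolysis, catabolic processes	16.3	ALDOA,TPI1,LDHA,ALDOC,PFKP,PGK1,GAPDH,ENO1
Translation	16.3	NACA,RPL8,RPL3,UBC,EIF1,RPL11,RPS6,RPS8
Translational elongation	12.2	RPL8,RPL3,UBC,RPL11,RPS6,RPS8
Nitrogen compound biosynthetic process	12.2	ALDOA,GLUL,ATP5B,ATP1A1,ATP5A1,ATP5G3
Cation transport	12.2	SLC4A11,ATP5B,TPT1,ATP1A1,ATP5A1,ATP5G3
Homeostatic process	12.2	ALDOA,HERPUD1,SLC4A11,ATP5B,TPT1,RPS6
ATP/nucleotide biosynthetic process	10.2	ALDOA,ATP5B,ATP1A1,ATP5A1,ATP5G3
Monovalent inorganic cation transport	10.2	SLC4A11,ATP5B,ATP1A1,ATP5A1,ATP5G3
Proton Transport	8.2	SLC4A11,ATP5B,ATP5A1,ATP5G3
Response to protein stimulus	8.2	HSP90AB1,FOS,HERPUD1,HSPA8
Organic aid biosynthetic process	8.2	TPI1,GLUL,PTGDS,SCD
Response to extracellular stimulus	8.2	FOS,LDHA,COZ4I1,MGP
Cation homeostasis	8.2	HERPUD1,SLC4A11,ATP5B,TPT1
Fructose metabolic process	6.1	ALDOA,ALDOC,PFKP
ATP synthesis coupled proton transport, ion transmembrane transport	6.1	ATP5B,ATP5A1,ATP5G3
Response to unfolded protein	6.1	HSP90AB1,HERPUD1,HSPA8
Fatty acid biosynthetic process	6.1	TPI1,PTGDS,SCD
Oxidative phosphorylation	6.1	ATP5B,ATP5A1,ATP5G3
Aging	6.1	FOS,ALDOC,ATP5G3
One-carbon metabolic process	6.1	FOS,CA12,CA3
Biosynthetic/metabolic processes	4.1	ATP5B,ATP5A1
Protein homotetramerization	4.1	ALDOC,PFKP
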