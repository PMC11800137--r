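chrom	pos	ref	alt	gene	hgvs_c	hgvs_p	consequence	ExAC_AF	gnomAD_AF	KG1000_AF	SIFT	PolyPhen2	CADD_phred	CADD_raw	GERP++RS	M-CAP	LoFtool	Condel	DANN	FATHMM	LRT	MetaLR	MutationTaster	PROVEAN
4	186595497	C	T	SORBS2	c.566C>T	p.T189M	missense	0.00003295	0.00001589	0.0001997	0.001	0.998	27.4	3.81	5.21	0.043	0.693	neutral	T	D	D	D	D	D
1	43916240	G	A	WDR65	c.3350G>A	p.R1117Q	missense	0.00019	0.00011	.	0.012	0.91	24.1	3.2	4.6	0.012	0.88	neutral	T	D	N	T	D	N
5	32384001	A	G	ZFR	c.1100A>G	p.N367S	missense	0.00008	0.00006	0.0002	0.02	0.44	22.7	2.9	2.1	0.031	0.71	neutral	T	T	D	D	N	D
5	52347600	C	T	ITGA2	c.2269C>T	p.R757C	missense	0.00031	0.00024	.	0.09	0.86	23.5	1.7	4.9	0.008	0.63	deleterious	D	T	N	T	N	D
7	30645500	G	A	GARS	c.2212G>A	p.E738K	missense	0.00012	0.00007	0.0004	0.03	0.52	18.9	2.4	3.2	0.015	0.31	neutral	T	D	D	T	A	N
15	42440800	C	T	PLA2G4F	c.1459C>T	p.R487C	missense	0.00044	0.00029	.	0.21	0.61	21.3	1.9	4.3	0.029	0.77	neutral	D	T	N	D	N	N
15	43295300	C	T	UBR1	c.2480C>T	p.S827L	missense	0.00025	0.00018	0.0006	0.18	0.83	16.2	2.2	1.4	0.004	0.59	deleterious	T	T	N	T	N	D
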