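##fileformat=VCFv4.2
##source=pedprio synthetic candidate fixture (coordinates and genotypes reconstructed)
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	II-1	III-2	III-3	III-4	III-5	II-2	III-8
1	43916240	.	G	A	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/1	0/0	0/0
4	186595497	rs374906705	C	T	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/1	0/0	0/0
5	32384001	.	A	G	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/1	0/0	0/0
5	52347600	.	C	T	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/1	0/0	0/0
7	30645500	.	G	A	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/1	0/0	0/0
15	42440800	.	C	T	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/1	0/0	0/0
15	43295300	.	C	T	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/1	0/0	0/0
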