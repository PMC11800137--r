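# SYNTHETIC pedigree reconstruction: a four-generation, 23-member family
# segregating a fully penetrant dominant trait; 8 affected (incl. the
# deceased founder I-1), 11 unaffected, 4 of uncertain status (phenotype 0).
# The seven sequenced members (II-1, III-2..III-5 affected; II-2 aunt and
# III-8 cousin unaffected) sit in their reported relationships; the rest of
# the topology is constructed, not observed.
FAM1	I-1	0	0	1	2
FAM1	I-2	0	0	2	1
FAM1	II-1	I-1	I-2	2	2
FAM1	II-2	I-1	I-2	2	1
FAM1	II-3	0	0	1	1
FAM1	II-4	0	0	1	1
FAM1	III-1	II-3	II-1	1	2
FAM1	III-2	II-3	II-1	2	2
FAM1	III-3	II-3	II-1	2	2
FAM1	III-4	II-3	II-1	2	2
FAM1	III-5	II-3	II-1	2	2
FAM1	III-6	II-3	II-1	1	2
FAM1	III-7	II-3	II-1	1	0
FAM1	III-8	II-4	II-2	2	1
FAM1	III-9	0	0	1	1
FAM1	III-10	0	0	1	1
FAM1	IV-1	III-9	III-2	1	0
FAM1	IV-2	III-9	III-2	2	0
FAM1	IV-3	III-10	III-3	1	0
FAM1	IV-4	III-10	III-3	2	1
FAM1	IV-5	III-10	III-3	1	1
FAM1	IV-6	III-10	III-3	2	1
FAM1	IV-7	III-10	III-3	1	1
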