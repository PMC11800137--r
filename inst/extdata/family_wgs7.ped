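# Seven genome-sequenced members of the early-onset dementia family:
# five affected heterozygote-carrier relatives (mother II-1, proband III-2,
# sisters III-3/III-4/III-5) and two cognitively normal relatives
# (aunt II-2, cousin III-8). Parents outside this subset are coded 0.
FAM1	II-1	0	0	2	2
FAM1	II-2	0	0	2	1
FAM1	III-2	0	II-1	2	2
FAM1	III-3	0	II-1	2	2
FAM1	III-4	0	II-1	2	2
FAM1	III-5	0	II-1	2	2
FAM1	III-8	0	II-2	2	1
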