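position,allele1,allele2
110,T,C
113,A,G
263,C,T
277,C,G
432,G,A
572,T,C
707,G,C
1112,C,G
1220,C,T
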