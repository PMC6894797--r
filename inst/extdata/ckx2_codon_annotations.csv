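position,region,codon,codon_position
110,upstream,NA,NA
113,upstream,NA,NA
263,exon1,46,2
277,exon1,51,1
432,exon1,102,3
572,exon1,149,2
707,exon1,194,2
1112,exon2,296,3
1220,exon2,332,3
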