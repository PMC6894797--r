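haplotype,p110,p113,p263,p277,p432,p572,p707,p1112,p1220,wild,landrace
1,T,A,C,C,G,T,G,C,C,67,165
2,T,A,C,C,G,T,G,G,T,43,11
3,C,A,T,C,A,C,G,G,T,51,0
4,T,G,C,C,G,T,G,C,C,2,9
5,T,A,C,G,G,T,C,C,C,3,7
6,T,A,C,C,G,T,G,C,T,0,4
7,T,A,T,C,G,T,G,C,C,1,2
8,T,A,C,C,G,T,G,G,C,1,0
9,T,G,C,G,G,T,C,C,C,0,1
10,T,G,C,C,G,T,G,G,T,0,1
11,C,A,C,C,G,T,G,G,C,1,0
12,C,A,C,C,G,T,G,G,T,1,0
13,C,A,T,C,G,C,G,G,C,1,0
14,C,A,T,C,G,T,G,G,T,1,0
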