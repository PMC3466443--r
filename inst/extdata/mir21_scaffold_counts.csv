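scaffold_no,actives,inactives
1,19,86
2,14,97
3,15,623
4,13,628
5,14,692
6,14,878
7,28,2186
8,14,1140
9,12,1090
10,21,1999
11,14,1356
12,10,1086
13,11,1405
14,14,1852
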