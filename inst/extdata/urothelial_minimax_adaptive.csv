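S,n2,n_total,r
0,0,28,0
1,0,28,0
2,0,28,0
3,0,28,0
4,0,28,0
5,0,28,0
6,0,28,0
7,0,28,0
8,0,28,0
9,0,28,0
10,21,49,21
11,21,49,21
12,21,49,21
13,21,49,21
14,19,47,20
15,18,46,20
16,0,28,0
17,0,28,0
18,0,28,0
19,0,28,0
20,0,28,0
21,0,28,0
22,0,28,0
23,0,28,0
24,0,28,0
25,0,28,0
26,0,28,0
27,0,28,0
28,0,28,0
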