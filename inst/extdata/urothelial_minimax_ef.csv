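S,n2,n_total,r
0,0,32,0
1,0,32,0
2,0,32,0
3,0,32,0
4,0,32,0
5,0,32,0
6,0,32,0
7,0,32,0
8,0,32,0
9,0,32,0
10,0,32,0
11,0,32,0
12,17,49,21
13,17,49,21
14,17,49,21
15,17,49,21
16,17,49,21
17,0,32,0
18,0,32,0
19,0,32,0
20,0,32,0
21,0,32,0
22,0,32,0
23,0,32,0
24,0,32,0
25,0,32,0
26,0,32,0
27,0,32,0
28,0,32,0
29,0,32,0
30,0,32,0
31,0,32,0
32,0,32,0
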