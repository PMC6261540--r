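index,x_deg,y_deg,blind_spot
0,0,28,0
1,0,24,0
2,-20,20,0
3,-12,20,0
4,-4,20,0
5,4,20,0
6,12,20,0
7,20,20,0
8,0,16,0
9,-20,12,0
10,-12,12,0
11,-4,12,0
12,4,12,0
13,12,12,0
14,20,12,0
15,0,8,0
16,-28,4,0
17,-20,4,0
18,-12,4,0
19,-4,4,0
20,4,4,0
21,12,4,0
22,20,4,0
23,28,4,0
24,-2,2,0
25,2,2,0
26,-24,0,0
27,-16,0,0
28,-8,0,0
29,0,0,0
30,8,0,0
31,16,0,0
32,24,0,0
33,-2,-2,0
34,2,-2,0
35,-28,-4,0
36,-20,-4,0
37,-12,-4,0
38,-4,-4,0
39,4,-4,0
40,12,-4,0
41,20,-4,0
42,28,-4,0
43,0,-8,0
44,-20,-12,0
45,-12,-12,0
46,-4,-12,0
47,4,-12,0
48,12,-12,0
49,20,-12,0
50,0,-16,0
51,-20,-20,0
52,-12,-20,0
53,-4,-20,0
54,4,-20,0
55,12,-20,0
56,20,-20,0
57,0,-24,0
58,0,-28,0
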