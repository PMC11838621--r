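raw,t
6,22
7,23.6
8,25.2
9,26.8
10,28.4
11,30
12,31.6
13,33.2
14,34.8
15,36.4
16,38
17,39.6
18,41.2
19,42.8
20,44.4
21,46
22,47.6
23,49.2
24,50.8
25,52.4
26,54
27,55.6
28,57.2
29,58.8
30,60.4
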