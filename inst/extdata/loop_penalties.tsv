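n1	n2	penalty
0	1	3.8
1	0	3.8
0	2	2.8
2	0	2.8
1	1	1
1	2	1.6
2	1	1.6
2	2	1.1
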