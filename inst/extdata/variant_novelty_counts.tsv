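min_depth	n_total	n_novel
0	19188	12367
4	10052	6662
6	3247	1939
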