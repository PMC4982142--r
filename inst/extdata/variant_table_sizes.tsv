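sample	total	intergenic	intron	utr5	utr3	coding
BTAMix	6068678	4518518	1501565	1337	15213	32045
CPYB	344775	262448	80987	0	0	1340
CPYB-CCA	297042	226421	69282	0	0	1339
MGOB	1332441	991640	327012	27	2780	10982
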