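sample	category	n_all	n_het
BTAMix	total	19188	6374
BTAMix	intergenic	14829	4970
BTAMix	intron	4556	1474
BTAMix	utr5	4	2
BTAMix	utr3	49	18
BTAMix	coding_syn	46	8
BTAMix	coding_nonsyn	44	15
CPYB	total	15267	2915
CPYB	intergenic	12187	2349
CPYB	intron	3134	558
CPYB	utr5	0	0
CPYB	utr3	0	0
CPYB	coding_syn	17	3
CPYB	coding_nonsyn	26	10
CPYB-CCA	total	3086	1929
CPYB-CCA	intergenic	2476	1530
CPYB-CCA	intron	605	392
CPYB-CCA	utr5	0	0
CPYB-CCA	utr3	0	0
CPYB-CCA	coding_syn	1	1
CPYB-CCA	coding_nonsyn	12	9
MGOB	total	46592	1735
MGOB	intergenic	35292	1334
MGOB	intron	10102	320
MGOB	utr5	2	0
MGOB	utr3	101	8
MGOB	coding_syn	113	2
MGOB	coding_nonsyn	103	12
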