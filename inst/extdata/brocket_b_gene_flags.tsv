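region	gene_id	flag
chr1:80557678-80815945	LPP	(f)
chr1:132195520-132248825	PIK3CB	(f)
chr3:53939956-54035661	GFI1
chr3:97346492-97530439	ACOT11	(f)
chr3:97346492-97530439	SSBP3	(f)
chr5:112038039-112092762	CCND2
chr6:67475289-69302666	COX7B2
chr6:67475289-69302666	GABRA4
chr6:67475289-69302666	GABRB1	(f?)
chr6:67475289-69302666	LOC536190	(f?)
chr6:67475289-69302666	ATP10D
chr6:67475289-69302666	NFXL1
chr6:67475289-69302666	CNGA1
chr6:67475289-69302666	NIPAL1
chr6:67475289-69302666	TXK
chr6:72725708-72802304	KIT	(f)
chr6:101762919-101983089	COQ2
chr6:101762919-101983089	HPSE
chr6:101762919-101983089	MIR2446
chr6:101762919-101983089	MRPS18C
chr6:101762919-101983089	FAM175A	(f)
chr6:115148215-115688073	MIR2448
chr6:115148215-115688073	FBXL5
chr6:115148215-115688073	CD38	(f?)
chr6:115148215-115688073	FGFBP1
chr7:11112904-11187619	MAN2B1	(f)
chr8:78145-782808	ANXA10
chr8:78145-782808	MIR2466
chr10:28363651-29133083	TMCO5B
chr14:5823596-6377396	KHDRBS3	(f)
chr17:46546364-46775437	MBD3L1
chr17:46546364-46775437	CHFR
chr17:46546364-46775437	ZNF268	(f)
chr19:59129525-59366644	CDC42EP4
chr19:59129525-59366644	FAM104A
chr19:59129525-59366644	COG1	(f)
chr22:1765826-1920639	EOMES	(f)
chr22:11626319-11984586	ACAA1
chr22:11626319-11984586	MYD88
chr22:11626319-11984586	OXSR1
chr22:11626319-11984586	XYLB
chr22:11626319-11984586	ACVR2B
chr22:11626319-11984586	DLEC1	(f)
chr23:8994141-9084277	C23H6orf106	(f)
chr23:8994141-9084277	SNRPC	(f)
chr23:50678412-50701238	SERPINB9
chr28:628155-915003	TRIM67
chr28:628155-915003	FAM89A
chr28:628155-915003	ARV1
chr28:628155-915003	TTC13	(f)
chr28:12110619-12174951	RET
chr29:34728621-35503130	OPCML	(f)
chr29:49338779-50252639	DHCR7	(f?)
chr29:49338779-50252639	NADSYN1
chr29:49338779-50252639	CARS	(f)
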