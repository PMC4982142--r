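region	gene_id	flag
chr3:74548027-76486586	LRRIQ3
chr3:74548027-76486586	FPGT
chr3:74548027-76486586	TNNI3K	(f)
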