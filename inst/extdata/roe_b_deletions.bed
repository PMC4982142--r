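chr3	74880000	75300000
chr3	75680000	75820000
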