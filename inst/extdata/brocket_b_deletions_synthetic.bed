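chr6	67900000	68003000
chr6	68700000	68803000
chr6	115400000	115503000
chr8	400000	503000
chr10	28600000	28703000
chr14	6000000	6103000
chr22	11750000	11853000
chr28	700000	803000
chr29	35000000	35103000
chr29	49600000	49703000
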