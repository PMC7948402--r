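chr1	0	700	2
chr1	9000	14200	1.5
chr2	400	4600	3
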