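chr1	100	600	geneA	0	+
chr1	9000	14000	geneB	0	-
chr2	500	4500	geneC	0	+
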