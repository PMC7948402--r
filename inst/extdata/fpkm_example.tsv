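gene_id	fpkm
geneA	12.5
geneB	6.1
geneC	2.4
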