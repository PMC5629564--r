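chr1	2500	3000	geneA	0	+
chr1	3500	4000	geneB	0	+
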