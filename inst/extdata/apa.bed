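chr1	1000	1200	geneA_PRE	0	+
chr1	1200	1300	geneA_POST	0	+
chr1	2000	2200	geneB_PRE	0	+
chr1	2200	2350	geneB_POST	0	+
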