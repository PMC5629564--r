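chr1	toy	exon	1001	1200	.	+	.	gene_id "geneA";
chr1	toy	exon	1501	1700	.	+	.	gene_id "geneA";
chr1	toy	exon	1651	1900	.	+	.	gene_id "geneB";
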