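chr1	30000000	31000000	GENE_A
chr1	100000000	101000000	GENE_B
chr2	20000000	21000000	GENE_C
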