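chrom	length	cen_start	cen_end
chr1	120000000	58000000	62000000
chr2	120000000	58000000	62000000
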