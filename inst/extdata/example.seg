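sample	chrom	start	end	cn
S1	chr1	1	58000000	0.32
S1	chr1	62000001	120000000	0.02
S1	chr2	1	120000000	-0.01
S2	chr1	1	25000000	0.01
S2	chr1	25000001	58000000	0.03
S2	chr1	62000001	120000000	-0.38
S2	chr2	1	18000000	0.05
S2	chr2	18000001	23000000	1.15
S2	chr2	23000001	120000000	0.04
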