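#cytoband	chrom	start	end
chr1p1	chr1	1	1500000
chr1q1	chr1	1500001	3000000
chr1q2	chr1	3000001	6000000
chr2p1	chr2	1	2000000
chr2q1	chr2	2000001	6000000
chr3p1	chr3	1	3000000
chr3q1	chr3	3000001	6000000
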