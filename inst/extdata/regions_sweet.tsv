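scaffold	start	end	size	markers	gene_number
CM3.5_scaffold0001	5372000	5401000	29000	SLAF3367,SLAF3370	2
CM3.5_scaffold0004	5312000	5319000	7000	SLAF6320,SLAF6321	0
CM3.5_scaffold0006	861000	875000	14000	SLAF8215,SLAF8216	2
CM3.5_scaffold0016	1793000	2126000	333000	SLAF18729,SLAF18745,SLAF18775	54
CM3.5_scaffold0023	2740000	2845000	105000	SLAF24883,SLAF24901	4
CM3.5_scaffold0045	1181000	1195000	14000	SLAF38671,SLAF38677	0
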