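chrom	marker_id	start	end
chr06	SLAF8215	861471	861868
chr06	SLAF8216	874069	874414
chr06	SLAF24883	16359185	16359588
chr06	SLAF24901	16462572	16462949
chr10	SLAF18729	3871880	3872260
chr10	SLAF18745	3766227	3766593
chr10	SLAF18775	3540166	3540533
chr11	SLAF38671	2006296	2006657
chr11	SLAF38677	1993550	1993930
chr12	SLAF3367	19603319	19603727
chr12	SLAF3370	19575933	19576314
chr12	SLAF6320	7090425	7090799
chr12	SLAF6321	7085133	7085501
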