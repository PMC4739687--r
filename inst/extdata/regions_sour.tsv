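scaffold	start	end	size	markers	gene_number
CM3.5_scaffold00003	2631000	2653000	22000	SLAF4675,SLAF4679	0
CM3.5_scaffold00003	3188000	3256000	68000	SLAF4736,SLAF4745	4
CM3.5_scaffold00004	7621000	7864000	243000	SLAF6659,SLAF6693	15
CM3.5_scaffold00009	7143000	7243000	100000	SLAF12456,SLAF12467	2
CM3.5_scaffold00011	4255000	4504000	249000	SLAF14408,SLAF14409,SLAF14440	33
CM3.5_scaffold00018	3724000	3750000	26000	SLAF20908,SLAF20910	2
CM3.5_scaffold00018	4157000	4183000	26000	SLAF20972,SLAF20979	1
CM3.5_scaffold00018	5769000	5845000	76000	SLAF21206,SLAF21215	8
CM3.5_scaffold00018	5874000	5947000	73000	SLAF21222,SLAF21231	4
CM3.5_scaffold00024	2947000	2955000	8000	SLAF25822,SLAF25825	1
CM3.5_scaffold00032	4022000	4025000	3000	SLAF31553,SLAF31554	0
CM3.5_scaffold00040	2861000	2988000	127000	SLAF36320,SLAF36334	6
CM3.5_scaffold00054	362000	438000	76000	SLAF42241,SLAF42254	2
CM3.5_scaffold00054	833000	987000	154000	SLAF42301,SLAF42321	7
CM3.5_scaffold00054	1441000	1480000	39000	SLAF42384,SLAF42394	0
CM3.5_scaffold00054	1920000	2240000	320000	SLAF42476,SLAF42498,SLAF42509	29
CM3.5_scaffold00054	2287000	2313000	26000	SLAF42523,SLAF42526	0
CM3.5_scaffold00055	2323000	2397000	74000	SLAF42926,SLAF42936	5
CM3.5_scaffold00083	196000	261000	65000	SLAF50072,SLAF50085	7
CM3.5_scaffold00088	141000	253000	112000	SLAF50944,SLAF50974	5
CM3.5_scaffold00089	595000	867000	272000	SLAF51212,SLAF51247	42
CM3.5_scaffold00095	491000	496000	5000	SLAF52032,SLAF52035	0
CM3.5_scaffold00114	53000	120000	67000	SLAF53315,SLAF53325	12
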