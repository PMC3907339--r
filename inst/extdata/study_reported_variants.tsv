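variant_id	gene	mac	maf_printed	is_array
rs2575875	ABCA1	4209	0.30	TRUE
rs2066718	ABCA1	181	0.015	FALSE
rs2066715	ABCA1	674	0.055	FALSE
rs3764261	CETP	3913	0.27	TRUE
rs5883	CETP	490	0.040	FALSE
rs5880	CETP	296	0.024	FALSE
rs2303790	CETP	7	0.00057	FALSE
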