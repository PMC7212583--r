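matrix_id	gene_symbol	tfclass_family	cisbp_family
EX1	ELK1	3.5.2 Ets-related	Ets
EX2	HOXA1	3.1.1 HOX-related	Homeodomain
example_cisbp_matrix	SP1	2.3.1 Three-zinc-finger Kruppel-related	C2H2 ZF
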