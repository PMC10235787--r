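variant_id	gene_id	tissue	qval
rs00001	JAK1	Artery_Tibial	0.0012
rs00001	RPL3	Artery_Tibial	0.2400
rs00002	STAT1	Whole_Blood	0.0030
rs00002	STAT1	Artery_Aorta	0.0450
rs00003	TYK2	Whole_Blood	0.0001
rs00003	CDK1	Whole_Blood	0.4100
rs00004	IFNAR1	Artery_Aorta	0.0200
rs00005	SOCS1	Whole_Blood	0.0490
rs00006	JAK2	Artery_Tibial	0.0100
rs00006	JAK2	Whole_Blood	0.0800
rs00007	PDCD1	Whole_Blood	0.0400
rs00008	HLA-A	Whole_Blood	0.0600
rs00009	LDLR	Liver	0.0010
rs00010	ELN	Artery_Aorta	0.1200
rs00011	RPS6	Whole_Blood	0.030
rs00012	TP53	Whole_Blood	0.5000
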