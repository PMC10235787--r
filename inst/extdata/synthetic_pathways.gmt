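PW_IFN_JAKSTAT	Interferon alpha/beta signalling (synthetic)	JAK1	JAK2	TYK2	STAT1	STAT2	IFNAR1	IFNAR2	SOCS1	IRF9
PW_TCR	T cell receptor signalling (synthetic)	LCK	ZAP70	LAT	CD3E	CD28	PDCD1	CD274	FYN
PW_MHC1	Class I MHC antigen presentation (synthetic)	HLA-A	HLA-B	HLA-C	B2M	TAP1	TAP2	ERAP1
PW_LIPID	Plasma lipoprotein remodelling (synthetic)	LDLR	APOB	PCSK9	APOE	CETP	LPL
PW_ELASTIC	Elastic fibre formation (synthetic)	ELN	FBN1	FBN2	LOX	LTBP1
PW_ACH	Acetylcholine binding and downstream events (synthetic)	CHRNA3	CHRNA5	CHRNB4	CHRM2
PW_CELLCYCLE	Cell cycle checkpoints (synthetic)	CDK1	CDK2	CCNB1	TP53	RB1	E2F1
PW_RIBO	Translation housekeeping (synthetic)	RPL3	RPL4	RPS6	RPS19	EIF4E	EIF2S1	RPL11	RPS3	RPL23	RPS8
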