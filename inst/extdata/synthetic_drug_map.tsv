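pathway_id	drug	atc_code
PW_IFN_JAKSTAT	ruxolitinib	L01EJ01
PW_IFN_JAKSTAT	baricitinib	L04AA37
PW_IFN_JAKSTAT	tofacitinib	L04AA29
PW_IFN_JAKSTAT	interferon alfa	L03AB01
PW_TCR	nivolumab	L01FF01
PW_TCR	cemiplimab	L01FF06
PW_LIPID	atorvastatin	C10AA05
PW_ELASTIC	penicillamine	M01CC01
PW_UNKNOWN	placebo	V03AX
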