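ENSG00000166710	B2M
ENSG00000156508	EEF1A1
ENSG00000133112	TPT1
ENSG00000087086	FTL
ENSG00000228253	MT-ATP8
ENSG00000234745	HLA-B
ENSG00000204525	HLA-C
ENSG00000166598	HSP90B1
ENSG00000148346	LCN2
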