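gene_id	symbol
ENSG00000146648	EGFR
ENSG00000141736	ERBB2
ENSG00000065361	ERBB3
ENSG00000178568	ERBB4
ENSG00000177885	GRB2
ENSG00000160691	SHC1
ENSG00000121879	PIK3CA
ENSG00000051382	PIK3CB
ENSG00000145715	RASA1
ENSG00000115904	SOS1
ENSG00000100485	SOS2
ENSG00000109458	GAB1
ENSG00000142208	AKT1
ENSG00000105221	AKT2
ENSG00000117020	AKT3
ENSG00000174775	HRAS
ENSG00000133703	KRAS
ENSG00000213281	NRAS
ENSG00000132155	RAF1
ENSG00000157764	BRAF
ENSG00000078061	ARAF
ENSG00000169032	MAP2K1
ENSG00000126934	MAP2K2
ENSG00000196396	PTPN1
ENSG00000118260	CREB1
ENSG00000100030	MAPK1
ENSG00000102882	MAPK3
ENSG00000126767	ELK1
ENSG00000117676	RPS6KA1
ENSG00000071242	RPS6KA2
ENSG00000177189	RPS6KA3
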