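species	genes
ErbB1	EGFR
ErbB2	ERBB2
ErbB3	ERBB3
ErbB4	ERBB4
Grb2	GRB2
Shc	SHC1
PI3K	PIK3CA,PIK3CB
RasGAP	RASA1
SOS	SOS1,SOS2
Gab1	GAB1
Akt	AKT1,AKT2,AKT3
RasGDP	HRAS,KRAS,NRAS
Raf	RAF1,BRAF,ARAF
MEK	MAP2K1,MAP2K2
PTP1B	PTPN1
CREB	CREB1
ERK	MAPK1,MAPK3
Elk1	ELK1
RSK	RPS6KA1,RPS6KA2,RPS6KA3
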