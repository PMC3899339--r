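test_species	train_1	train_2	train_3	train_4
ECO	STY	PAU	BSU	CCS
STY	ECO	PAU	BSU	FTN
HIN	STY	PAU	SPO	SAO
VCH	ECO	PAU	SPO	FTN
PAU	VCH	CCS	ECO	FTN
ACI	PAU	SSA	ECO	CCS
FTN	VCH	PAU	ECO	BTH
HPY	PAU	STY	ECO	VCH
CCS	PAU	FTN	ECO	BTH
BSU	SAO	SPN	ECO	CCS
SAO	SPN	BSU	SCE	ECO
SPN	SAO	HIN	ECO	SSA
SSA	SAO	ACI	ECO	FTN
MGE	MPU	SAO	ECO	HIN
MPU	MGE	SAO	ECO	FTN
MTU	SAO	HIN	ECO	CCS
BTH	PGN	HIN	SCE	FTN
PGN	BTH	PAU	ECO	SAO
SCE	SPO	MGE	ECO	HPY
SPO	SCE	MGE	ECO	HPY
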