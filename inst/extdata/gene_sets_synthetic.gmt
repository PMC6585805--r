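FOCAL_ADHESION	synthetic focal-adhesion / integrin-proximal signalling set	PTK2	PTK2B	PXN	CTTN	EFS	CRK	RASA1	PECAM1	EPB41
PI3K_AKT	synthetic PI3K/AKT signalling set	PIK3R1	PDPK1	EGFR	KDR	FLT1	MET	RET	ERBB4	NTRK2
ERK_MAPK	synthetic ERK/MAPK cascade set	MAPK1	MAPK10	RAF1	EGFR	PDGFRB	FGFR3	CRK	RASA1	MST1R
IMMUNE_RECEPTOR	synthetic immune receptor-proximal kinase set	LCK	ZAP70	LAT	CD79A	NCF1	FES	FER	TEC	JAK1	JAK2	EPOR
CELL_CYCLE	synthetic cell-cycle regulation set	CDK2	CDK7	RB1	PPP2CB	CCNA2	CCNE1	CDC25A
CYTOSKELETON	synthetic cytoskeletal / structural substrate set	DCX	MBP	KRT6B	CTTN	ENO2	DYRK1A	ANXA1
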