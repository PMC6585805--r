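peptide_id	protein_label	gene_id	site_start	site_end	is_artificial_control	is_internal_positive_control
41_654_666	41	EPB41	654	666	FALSE	FALSE
ANXA1_14_26	ANXA1	ANXA1	14	26	FALSE	FALSE
ART_003_EAIYAAPFAKKKXC	ART_003_EAIYAAPFAKKKXC	NA	NA	NA	FALSE	TRUE
ART_004_EAIYAAPFAKKKXC	ART_004_EAIYAAPFAKKKXC	ABL1	NA	NA	TRUE	FALSE
CD79A_181_193	CD79A	CD79A	181	193	FALSE	FALSE
CDK2_8_20	CDK2	CDK2	8	20	FALSE	FALSE
CDK7_157_169	CDK7	CDK7	157	169	FALSE	FALSE
CRK_214_226	CRK	CRK	214	226	FALSE	FALSE
DCX_109_121	DCX	DCX	109	121	FALSE	FALSE
DYR1A_312_324	DYR1A	DYRK1A	312	324	FALSE	FALSE
EFS_246_258	EFS	EFS	246	258	FALSE	FALSE
EGFR_1165_1177	EGFR	EGFR	1165	1177	FALSE	FALSE
ENOG_37_49	ENOG	ENO2	37	49	FALSE	FALSE
EPHA1_774_786	EPHA1	EPHA1	774	786	FALSE	FALSE
EPHA2_765_777	EPHA2	EPHA2	765	777	FALSE	FALSE
EPHA7_607_619	EPHA7	EPHA7	607	619	FALSE	FALSE
EPHB1_771_783	EPHB1	EPHB1	771	783	FALSE	FALSE
EPHB1_921_933	EPHB1	EPHB1	921	933	FALSE	FALSE
EPOR_361_373	EPOR	EPOR	361	373	FALSE	FALSE
EPOR_419_431	EPOR	EPOR	419	431	FALSE	FALSE
ERBB4_1277_1289	ERBB4	ERBB4	1277	1289	FALSE	FALSE
FAK1_569_581	FAK1	PTK2	569	581	FALSE	FALSE
FAK2_572_584	FAK2	PTK2B	572	584	FALSE	FALSE
FER_707_719	FER	FER	707	719	FALSE	FALSE
FES_706_718	FES	FES	706	718	FALSE	FALSE
FGFR3_753_765	FGFR3	FGFR3	753	765	FALSE	FALSE
FRK_380_392	FRK	FRK	380	392	FALSE	FALSE
JAK1_1015_1027	JAK1	JAK1	1015	1027	FALSE	FALSE
JAK2_563_577	JAK2	JAK2	563	577	FALSE	FALSE
K2C6B_53_65	K2C6B	KRT6B	53	65	FALSE	FALSE
LAT_194_206	LAT	LAT	194	206	FALSE	FALSE
LAT_249_261	LAT	LAT	249	261	FALSE	FALSE
LCK_387_399	LCK	LCK	387	399	FALSE	FALSE
MBP_198_210	MBP	MBP	198	210	FALSE	FALSE
MET_1227_1239	MET	MET	1227	1239	FALSE	FALSE
MK01_180_192	MK01	MAPK1	180	192	FALSE	FALSE
MK10_216_228	MK10	MAPK10	216	228	FALSE	FALSE
NCF1_313_325	NCF1	NCF1	313	325	FALSE	FALSE
NTRK2_696_708	NTRK2	NTRK2	696	708	FALSE	FALSE
P85A_600_612	P85A	PIK3R1	600	612	FALSE	FALSE
PAXI_111_123	PAXI	PXN	111	123	FALSE	FALSE
PAXI_24_36	PAXI	PXN	24	36	FALSE	FALSE
PDPK1_2_14	PDPK1	PDPK1	2	14	FALSE	FALSE
PDPK1_369_381	PDPK1	PDPK1	369	381	FALSE	FALSE
PECA1_706_718	PECA1	PECAM1	706	718	FALSE	FALSE
PGFRB_1002_1014	PGFRB	PDGFRB	1002	1014	FALSE	FALSE
PGFRB_1014_1028	PGFRB	PDGFRB	1014	1028	FALSE	FALSE
PGFRB_572_584	PGFRB	PDGFRB	572	584	FALSE	FALSE
PGFRB_709_721	PGFRB	PDGFRB	709	721	FALSE	FALSE
PGFRB_768_780	PGFRB	PDGFRB	768	780	FALSE	FALSE
PGFRB_771_783	PGFRB	PDGFRB	771	783	FALSE	FALSE
PLCG1_764_776	PLCG1	PLCG1	764	776	FALSE	FALSE
PP2AB_297_309	PP2AB	PPP2CB	297	309	FALSE	FALSE
PRRX2_202_214	PRRX2	PRRX2	202	214	FALSE	FALSE
PTN11_539_551	PTN11	PTPN11	539	551	FALSE	FALSE
RAF1_332_344	RAF1	RAF1	332	344	FALSE	FALSE
RASA1_453_465	RASA1	RASA1	453	465	FALSE	FALSE
RB_804_816	RB	RB1	804	816	FALSE	FALSE
RET_1022_1034	RET	RET	1022	1034	FALSE	FALSE
RON_1346_1358	RON	MST1R	1346	1358	FALSE	FALSE
SRC8_CHICK_476_488	SRC8_CHICK	CTTN	476	488	FALSE	FALSE
SRC8_CHICK_492_504	SRC8_CHICK	CTTN	492	504	FALSE	FALSE
TEC_512_524	TEC	TEC	512	524	FALSE	FALSE
TYRO3_679_691	TYRO3	TYRO3	679	691	FALSE	FALSE
VGFR1_1326_1338	VGFR1	FLT1	1326	1338	FALSE	FALSE
VGFR2_944_956	VGFR2	KDR	944	956	FALSE	FALSE
VGFR2_989_1001	VGFR2	KDR	989	1001	FALSE	FALSE
ZAP70_485_497	ZAP70	ZAP70	485	497	FALSE	FALSE
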