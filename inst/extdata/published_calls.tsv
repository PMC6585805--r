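peptide_id	ecm_class	ti_class
ART_004_EAIYAAPFAKKKXC	early	early
CD79A_181_193	early	early
CDK2_8_20	early	early
CDK7_157_169	early	early
DCX_109_121	early	early
EFS_246_258	early	early
ENOG_37_49	early	early
EPHA1_774_786	early	early
EPHA2_765_777	early	early
EPHB1_921_933	early	early
FER_707_719	early	early
FES_706_718	early	early
FRK_380_392	early	early
K2C6B_53_65	early	early
MBP_198_210	early	early
MK10_216_228	early	early
NCF1_313_325	early	early
NTRK2_696_708	early	early
P85A_600_612	early	early
PAXI_111_123	early	early
PAXI_24_36	early	early
PDPK1_2_14	early	early
PECA1_706_718	early	early
PGFRB_572_584	early	early
PLCG1_764_776	early	early
RAF1_332_344	early	early
RB_804_816	early	early
RET_1022_1034	early	early
SRC8_CHICK_476_488	early	early
SRC8_CHICK_492_504	early	early
TYRO3_679_691	early	early
VGFR2_944_956	early	early
VGFR2_989_1001	early	early
41_654_666	early	mid
EPHA7_607_619	early	mid
JAK2_563_577	early	mid
LAT_249_261	early	mid
PDPK1_369_381	early	mid
VGFR1_1326_1338	early	late
DYR1A_312_324	early	none
MK01_180_192	early	none
PGFRB_709_721	early	none
PP2AB_297_309	early	none
FAK2_572_584	mid	early
PRRX2_202_214	mid	early
RASA1_453_465	mid	early
EPHB1_771_783	mid	mid
LCK_387_399	mid	mid
MET_1227_1239	mid	mid
ANXA1_14_26	mid	late
EGFR_1165_1177	mid	late
EPOR_361_373	mid	late
EPOR_419_431	mid	late
PGFRB_1002_1014	mid	late
PGFRB_1014_1028	mid	late
PGFRB_771_783	mid	late
ZAP70_485_497	mid	late
FAK1_569_581	mid	none
LAT_194_206	mid	none
TEC_512_524	late	mid
FGFR3_753_765	late	late
CRK_214_226	late	none
JAK1_1015_1027	late	none
PTN11_539_551	none	early
RON_1346_1358	none	mid
ERBB4_1277_1289	none	late
PGFRB_768_780	none	late
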