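snp	genotype	label	control	UADT_inside	UADT_outside
MPO_G463A	0	GG	141	70	7
MPO_G463A	1	GA	45	34	6
MPO_G463A	2	AA	10	9	4
SULT1A1_Arg213His	0	Arg/Arg	132	60	4
SULT1A1_Arg213His	1	Arg/His	60	43	13
SULT1A1_Arg213His	2	His/His	2	6	0
mEH_Tyr113His	0	Tyr/Tyr	78	25	6
mEH_Tyr113His	1	Tyr/His	95	53	6
mEH_Tyr113His	2	His/His	22	18	3
hOGG1_Ser326Cys	0	Ser/Ser	114	49	7
hOGG1_Ser326Cys	1	Ser/Cys	62	51	7
hOGG1_Ser326Cys	2	Cys/Cys	14	8	3
XRCC1_Arg280His	0	Arg/Arg	157	80	14
XRCC1_Arg280His	1	Arg/His	33	30	2
XRCC1_Arg280His	2	His/His	4	4	1
BRCA2_Asn372His	0	Asn/Asn	81	30	5
BRCA2_Asn372His	1	Asn/His	70	50	6
BRCA2_Asn372His	2	His/His	35	14	4
CCND1_A870G	0	GG	67	33	11
CCND1_A870G	1	GA	93	55	4
CCND1_A870G	2	AA	45	27	2
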