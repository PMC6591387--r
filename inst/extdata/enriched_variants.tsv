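gene	hg19	protein_change	consequence	ref_af	ref_ac	ref_ac_hom	cadd_phred	ms_ac	ms_ac_hom	ctrl_ac	ctrl_ac_hom
CARD18	11_105009760_C_A	p.Gly18Val	missense	1.63E-05	4	0	11.83	3	0	0	0
CHUK	10_101959733_G_A	p.Pro575Leu	missense	1.63E-05	4	0	24.4	2	0	0	0
DHX58	17_40257832_CTG_-	p.Gln391del	inframe_indel	4.11E-06	1	0		2	0	0	0
DUSP1	5_172197790_C_T	p.Ala56Thr	missense	0.022276	2192	36	22.7	12	0	6	0
HDAC6	X_48681187_G_A	p.Arg832His	missense	0.023789	4046	39	23.9	17	14	7	4
IFIH1	2_163134090_C_A	p.Glu627*	stop_gained	0.003199	786	1	38	7	0	1	0
IL4	5_132015548_G_A	p.Arg109Gln	missense	7.76E-05	19	0	14.77	2	0	0	0
LRRFIP1	2_238671578_T_C	p.Ser408Pro	missense	2.44E-05	6	0	2.929	2	0	0	0
CGAS	6_74161604_C_T	p.Gly101Arg	missense	0.015178	2080	25	8.006	11	0	5	0
NLRP1	17_5424908_C_T	p.Arg1240His	missense	4.47E-05	11	0	0.108	3	0	0	0
PTPRC	1_198718604_G_A	p.Asp1000Asn	missense	0.000193	47	0	28.5	3	0	1	0
SIRT2	19_39379770_C_T	p.Arg153His	missense	0.008683	2129	19	34	9	2	3	0
TBK1	12_64891037_G_C	p.Glu653Gln	missense	0.000254	56	0	18.96	2	0	0	0
TICAM1	19_4816670_G_C	p.Leu574Val	missense	0.000138	34	0	0.001	2	0	0	0
ZBP1	20_56195349_C_T	p.Met1?	start_lost	0.014182	3042	32	13.4	11	0	4	0
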