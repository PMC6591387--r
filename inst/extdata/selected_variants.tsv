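gene	hg19	protein_change	consequence	ref_af	ref_ac	cadd_phred	ms_ac	ctrl_ac	ms_enriched
CASP1	11_104901069_A_-	p.Asn205fs	frameshift	4.10E-06	1		1	0	FALSE
CASP8	2_202131331_C_A	p.Ala100Asp	missense		0	24.4	1	0	FALSE
DHX58	17_40257124_G_C	p.Thr438Arg	missense	4.07E-06	1	26.7	1	0	FALSE
EIF2AK2	2_37336412_T_A	p.Glu468Asp	missense		0	25.4	1	0	FALSE
FOXO3	6_108985199_A_G	p.Asp388Gly	missense	4.06E-06	1	23.3	1	0	FALSE
HDAC6	X_48681075_A_G	p.Thr795Ala	missense		0	25.5	0	1	FALSE
HSP90AB1	6_44220815_T_G	p.Cys589Gly	missense	4.08E-06	1	22.3	1	0	FALSE
IFIH1	2_163134114_T_C	p.Met619Val	missense	8.14E-06	2	24.4	2	0	TRUE
MEFV	16_3304478_-_C	p.Gln198fs	frameshift		0		1	0	FALSE
NLRP1	17_5445285_T_-	p.Asn864fs	frameshift		0		1	0	FALSE
NLRP3	1_247588351_C_A	p.Leu536Met	missense		0	24	1	0	FALSE
POLR3A	10_79741230_C_T	p.Asp1283Asn	missense	8.13E-06	2	35	1	0	FALSE
POLR3A	10_79769710_C_T	p.Arg561Gln	missense	8.12E-06	2	35	1	0	FALSE
POLR3A	10_79745740_G_A	p.Arg998Cys	missense	8.12E-06	2	25.1	1	0	FALSE
POLR3A	10_79753041_T_G	p.Ile901Leu	missense		0	22.6	1	0	FALSE
POLR3A	10_79770247_T_G	p.Ile542Leu	missense		0	25.2	1	0	FALSE
POLR3A	10_79764601_T_C	p.Gln707Arg	missense	4.06E-06	1	22.6	1	0	FALSE
POP1	8_99161077_C_T	p.Pro582Leu	missense		0	33	1	0	FALSE
PTPN2	18_12794395_C_T	p.Arg377Gln	missense		0	27.2	1	0	FALSE
PTPN22	1_114399219_G_A	p.Ala144Val	missense		0	22.1	1	0	FALSE
PTPRC	1_198701436_C_T	p.Pro661Leu	missense	4.08E-06	1	34	1	0	FALSE
PTPRC	1_198665899_C_A	p.His53Gln	missense		0	22.9	1	0	FALSE
RIPK2	8_90782096_C_T	p.Pro194Ser	missense		0	32	2	0	TRUE
SIRT2	19_39371539_T_C	c.748-2A>G	splice_site		0	20.6	1	0	FALSE
SIRT2	19_39380575_G_A	p.Pro99Ser	missense	4.06E-06	1	25.7	1	0	FALSE
TYK2	19_10468526_C_T	p.Ala794Thr	missense		0	23.1	1	1	FALSE
TYK2	19_10479064_G_A	p.Ala75Val	missense	8.12E-06	2	25.3	1	0	FALSE
TYK2	19_10468793_C_T	p.Gly733Ser	missense	4.21E-06	1	25	1	0	FALSE
ULK1	12_132396530_C_T	p.Pro331Leu	missense	8.15E-06	2	25.7	0	1	FALSE
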