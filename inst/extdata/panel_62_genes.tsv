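gene
NLRP1
NLRP3
PYCARD
CASP1
EIF2AK2
DDX58
IFIH1
DHX58
TMEM173
ZBP1
POLR3A
CGAS
LRRFIP1
IRF3
IRF7
TYK2
JAK1
MAVS
STAT1
STAT2
MAPK8
FLI1
TICAM1
MYD88
TBK1
CHUK
IKBKE
HSP90AA1
HSP90AB1
HDAC6
NR1H4
CASP8
FADD
POP1
PYDC2
PYDC5
CARD16
CARD17
CARD18
BRCC3
MARCH7
FBXL2
MEFV
TRIM31
ATG5
LRRFIP2
BECN1
ATG16L1
MAP1LC3B
NOD2
RIPK2
SQSTM1
SESN2
ULK1
DUSP1
SIRT2
IL4
FOXO3
PTPN2
PTPN6
PTPN22
PTPRC
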