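gene	cluster
ACTR3B	5
ANLN	1
BAG1	NA
BCL2	2
BIRC5	1
BLVRA	NA
CCNB1	1
CCNE1	1
CDC20	1
CDC6	1
CDCA1	1
CDH3	3
CENPF	1
CEP55	1
CXXC5	2
EGFR	3
ERBB2	4
ESR1	2
EXO1	1
FGFR4	7
FOXA1	2
FOXC1	3
GPR160	6
GRB7	4
KIF2C	1
KNTC2	1
KRT14	3
KRT17	3
KRT5	3
MAPT	2
MDM2	NA
MELK	1
MIA	3
MKI67	1
MLPH	2
MMP11	NA
MYBL2	1
MYC	NA
NAT1	2
ORC6L	1
PGR	2
PHGDH	5
PTTG1	1
RRM2	1
SFRP1	3
SLC39A6	2
TMEM45B	6
TYMS	1
UBE2C	1
UBE2T	1
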