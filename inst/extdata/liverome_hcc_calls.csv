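gene_symbol,study_id,direction
A2M,study5,down
A2M,study7,down
A2M,study11,down
A2M,study18,down
ADH4,study17,down
ADH4,study18,down
ADH4,study19,down
ALB,study20,up
ALB,study6,down
ALB,study11,down
ALB,study18,down
APOA1,study20,up
APOA1,study11,down
APOA1,study12,down
BHMT,study5,down
BHMT,study8,down
BHMT,study12,down
BHMT,study19,down
COL1A2,study7,up
COL1A2,study15,up
COL1A2,study17,up
CYP3A4,study20,up
CYP3A4,study1,down
CYP3A4,study11,down
DUSP1,study11,up
DUSP1,study20,up
DUSP1,study14,down
DUSP1,study19,down
ECHS1,study21,up
ECHS1,study1,down
ECHS1,study11,down
ECHS1,study14,down
ECHS1,study18,down
FAM36A,study20,up
FAM36A,study11,down
FAM36A,study21,down
FGB,study11,down
FGB,study17,down
FGB,study18,down
FGG,study1,down
FGG,study11,down
FGG,study21,down
FN1,study5,up
FN1,study13,up
FN1,study16,up
GMFG,study11,up
GMFG,study18,up
GMFG,study19,up
GPC3,study4,up
GPC3,study6,up
GPC3,study10,up
GPC3,study15,up
GPC3,study17,up
GPC3,study20,up
HAMP,study20,up
HAMP,study6,down
HAMP,study11,down
HGFAC,study5,down
HGFAC,study14,down
HGFAC,study17,down
HGFAC,study18,down
HPD,study6,down
HPD,study17,down
HPD,study18,down
HPD,study19,down
HSD17B6,study1,down
HSD17B6,study10,down
HSD17B6,study18,down
IGFBP3,study2,down
IGFBP3,study5,down
IGFBP3,study11,down
LCN2,study3,up
LCN2,study5,up
LCN2,study15,up
MT1F,study20,up
MT1F,study8,down
MT1F,study10,down
MT1F,study17,down
MT2A,study20,up
MT2A,study6,down
MT2A,study8,down
MT2A,study18,down
MT3,study5,down
MT3,study7,down
MT3,study8,down
MT3,study19,down
PCK1,study8,down
PCK1,study12,down
PCK1,study18,down
PCK1,study19,down
PLG,study5,down
PLG,study7,down
PLG,study10,down
PLG,study16,down
PRPSAP1,study11,up
PRPSAP1,study15,up
PRPSAP1,study19,up
RHOB,study16,up
RHOB,study5,down
RHOB,study7,down
SAA2,study1,down
SAA2,study6,down
SAA2,study19,down
SLC22A1,study20,up
SLC22A1,study6,down
SLC22A1,study10,down
SLC22A1,study11,down
SLC22A1,study14,down
SPARC,study3,up
SPARC,study5,up
SPARC,study7,up
SPARC,study12,up
SPARC,study15,up
SPARC,study19,up
TDO2,study1,down
TDO2,study8,down
TDO2,study11,down
TDO2,study19,down
TUBA1B,study2,up
TUBA1B,study4,up
TUBA1B,study5,up
TUBA1B,study8,up
UBD,study4,up
UBD,study10,up
UBD,study12,up
UBD,study15,up
UBD,study17,up
UBD,study20,up
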