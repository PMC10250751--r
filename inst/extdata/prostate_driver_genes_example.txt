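# Editable EXAMPLE list of prostate-cancer driver gene symbols.
# Assembled from field-standard driver panels (AR axis, cell cycle, DNA
# repair, PI3K/AKT, Wnt, epigenetic and ubiquitin pathway genes); replace
# with your study's curated list.
AR
TP53
PTEN
RB1
BRCA1
BRCA2
ATM
ATR
CDK12
SPOP
FOXA1
MYC
MYCN
CTNNB1
APC
ARID2
ARID1A
KMT2C
KMT2D
KDM6A
CHD1
ERG
ETV1
ETV4
TMPRSS2
NKX3-1
MED12
AKT1
PIK3CA
PIK3CB
PIK3R1
PIK3R2
MTOR
TSC1
TSC2
MSH2
MSH6
MLH1
PMS2
PALB2
CDKN1B
CDKN2A
CCND1
ZFHX3
GNAS
IDH1
USP7
XPO1
MACROD2
KDR
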