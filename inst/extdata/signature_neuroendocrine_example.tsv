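gene	direction
SYP	1
CHGA	1
CHGB	1
ENO2	1
SOX2	1
PEG10	1
SRRM4	1
EZH2	1
MYCN	1
POU3F2	1
NCAM1	1
DLL3	1
AR	-1
KLK3	-1
NKX3-1	-1
REST	-1
TP53	-1
RB1	-1
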