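gene	direction
FASN	1
ACACA	1
ACLY	1
LDHA	1
FBP1	1
MAOA	1
CPT1A	1
SLC16A3	1
HK2	1
PKM	1
ACO2	-1
FH	-1
OGDH	-1
MT-CO1	-1
MT-CO2	-1
MT-CO3	-1
MT-ATP6	-1
MT-ATP8	-1
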