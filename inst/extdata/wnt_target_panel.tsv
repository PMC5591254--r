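gene	p_up_given_active	p_up_given_inactive	p_high_given_up	p_high_given_down
AXIN2
ASCL2
LGR5
MYC
CCND1
CD44
SOX9
EPHB2
EPHB3
EPHB4
BMP4
TCF7
LEF1
DKK1
NKD1
SP5
TDGF1
ZNRF3
RNF43
CEMIP
GLUL
MSX1
MSX2
ID2
JUN
FOSL1
MMP7
BIRC5
VEGFA
CLDN1
ENC1
ETS2
L1CAM
NOTUM
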