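gene	mode
ARX	XL
CC2D2A	AR
DNM1L	AD
FANCC	AR
FGFR3	AD
FOXG1	AD
GJC2	AD
GLI2	AD
KAT6B	AD
NF1	AD
NID1	AD
NSD1	AD
OFD1	XLD
PDHA1	XLD
PTCH1	AD
PTPN11	AD
SIX3	AD
SOX2	AD
STIL	AR
TUBA1A	AD
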