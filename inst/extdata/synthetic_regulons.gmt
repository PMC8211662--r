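HHEX	synthetic regulon	CER1	LEFTY1	LEFTY2	NOG	DKK1
FOXA2	synthetic regulon	APOA1	APOA2	FN1	COL4A1
FOXA3	synthetic regulon	GATA6	PDGFRA	S100A14	DKK4
HNF4A	synthetic regulon	APOA1	FN1	FILLER0001	FILLER0002
JUNB	synthetic regulon	ATF3	ANXA1	FILLER0003
SP5	synthetic regulon	DKK1	DKK4	SFRP1	FILLER0004
GSC	synthetic regulon	CHRD	NOG	FILLER0005
LHX1	synthetic regulon	CER1	HHEX	LEFTY1	FILLER0006
MIXL1	synthetic regulon	LEFTY2	NOG	FILLER0007	FILLER0008
MNX1	synthetic regulon	SOSTDC1	NCLN	FILLER0009
SOX21	synthetic regulon	SOX2	NANOG	FILLER0010
OTX2	synthetic regulon	POU5F1	SOX2	FILLER0011	FILLER0012
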