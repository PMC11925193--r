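gene	category
NR5A1	SF1
AKR1C3	DSD
APC	DSD
AXIN1	DSD
CBX2	DSD
CCDC59	DSD
CDH23	DSD
CITED2	both
COL1A1	DSD
COL9A3	DSD
DHRS7	DSD
DHX37	DSD
DKK1	DSD
ETNK2	DSD
FBLN2	DSD
FDXR	DSD
FLNB	DSD
GATA5	DSD
GLI2	DSD
GLI3	DSD
HHAT	DSD
INO80	DSD
KANK1	DSD
KAT6B	DSD
LGR5	DSD
LRP6	DSD
MAPK14	DSD
MKKS	DSD
MYO7A	DSD
NOS1	DSD
NR1H2	DSD
PDGFRA	DSD
PKD1	DSD
PLXNB1	DSD
PPARGC1B	DSD
PTCH1	DSD
RXFP2	DSD
SEMA6D	DSD
SFRP1	DSD
SPRY4	DSD
SRA1	both
SRCAP	DSD
SYNM	DSD
TBCE	DSD
TBX2	DSD
ZFPM2	DSD
ZNF462	DSD
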