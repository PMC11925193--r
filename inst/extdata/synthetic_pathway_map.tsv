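gene	pathway_id
NR5A1	P_gene_expression
NR5A1	P_developmental_biology
NR5A1	P_signal_transduction
NR5A1	P_protein_metabolism
NR5A1	P_ptm
CITED2	P_gene_expression
CBX2	P_gene_expression
GLI2	P_signal_transduction
GLI3	P_signal_transduction
APC	P_signal_transduction
AXIN1	P_signal_transduction
LRP6	P_signal_transduction
SFRP1	P_signal_transduction
DKK1	P_signal_transduction
PTCH1	P_developmental_biology
GATA5	P_gene_expression
ZFPM2	P_gene_expression
SRA1	P_gene_expression
NR1H2	P_ptm
FLNB	P_cytoskeleton
PKD1	P_cilium
CDH23	P_sensory
MYO7A	P_sensory
KAT6B	P_chromatin_other
TBCE	P_tubulin_folding
SPRY4	P_fgf_feedback
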