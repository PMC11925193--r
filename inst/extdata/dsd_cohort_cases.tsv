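case_id	family_id	source_table	karyotype	sex_of_rearing	phenotype_class	affection	anchor_hgvs_c	anchor_hgvs_p	anchor_zygosity	anchor_consequence	anchor_acmg	anchor_inheritance	anchor_pairable	anchor_flag
1	F01	1	46,XY	Female	Opposite sex-PGD	opposite_sex_DSD	NC_000009.11:g.(?_127243515)_(127269678_?)del		het	structural_deletion	P	unresolved	FALSE	anchor_not_pairable:whole_gene_deletion
2	F02	1	46,XY	Female	Opposite sex-CGD	opposite_sex_DSD	c.910_913delGAGC	p.Glu304Cysfs*29	het	frameshift	LP	maternal	TRUE
3	F03	1	46,XY	Male	Severe-NSDU	severe_DSD	c.1303del	p.Glu435Serfs*61	het	frameshift	LP	paternal	TRUE
4	F04	1	46,XY	Female	Severe-PGD	severe_DSD	c.946delC	p.Gln316Serfs*18	het	frameshift	LP	unresolved	TRUE
5	F05	1	46,XY	Male	Severe-PGD	severe_DSD	c.632_668del	p.Tyr211Cysfs*73	het	frameshift	LP	maternal	TRUE
6	F06	1	46,XY	Male	Severe-PGD	severe_DSD	c.630_637delGTACGGCT	p.Tyr211Profs*12	het	frameshift	LP	maternal	TRUE
7	F07	2	46,XY	Female	Opposite sex-CGD	opposite_sex_DSD	c.877G>A	p.Asp293Asn	hom_alt	missense	LP	unresolved	FALSE	anchor_not_pairable:homozygous_anchor
8	F08	2	46,XY	Female	Opposite sex-CGD	opposite_sex_DSD	c.1157_1211dup	p.Tyr404*	het	duplication	LP	unresolved	FALSE	anchor_not_pairable:large_duplication
9	F09	3	46,XY	Female	Opposite sex-CGD	opposite_sex_DSD	c.902G>A	p.Cys301Tyr	het	missense	LP	maternal	TRUE
10	F10	3	46,XY	Male	Severe-NSDU	severe_DSD	c.841C>T	p.Arg281Cys	het	missense	LP	unresolved	TRUE
11	F11	3	46,XY	Male	Severe-PGD	severe_DSD	c.1109G>A	p.Cys370Tyr	het	missense	LP	unresolved	TRUE
12	F12	3	46,XY	Female	Opposite sex-CGD	opposite_sex_DSD	c.217T>A	p.Cys73Ser	het	missense	LP	maternal	TRUE
13	F13	3	46,XY	Male	Severe-TDSD	severe_DSD	c.40C>T	p.Pro14Ser	het	missense	VUS	maternal	TRUE
14	F14	3	46,XY	Male	Severe-NSDU	severe_DSD	c.937C>T	p.Arg313Cys	het	missense	P	de_novo	TRUE
15	F15	3	46,XY	Female	Opposite sex-CGD	opposite_sex_DSD	c.614_615insC	p.Gln206Thrfs*20	het	frameshift	P	unresolved	TRUE
16	F16	3	46,XY	Female	Severe-TDSD	severe_DSD	c.102+1G>T		het	splice_site	LP	de_novo	TRUE
17	F17	3	46,XY	Male	Severe-TDSD	severe_DSD	c.938G>A	p.Arg313His	het	missense	P	unresolved	TRUE
18	F18	3	46,XY	Male	Severe-PGD	severe_DSD	c.937C>T	p.Arg313Cys	het	missense	P	paternal	TRUE
19	F19	3	46,XY	Female	Severe-PGD	severe_DSD	c.194G>A	p.Cys65Tyr	het	missense	LP	unresolved	TRUE
20	F20	3	46,XY	Male	Severe-PGD	severe_DSD	c.938G>A	p.Arg313His	het	missense	P	unresolved	TRUE
21	F21	3	46,XY	Male	Severe-PGD	severe_DSD	c.991-1G>A		het	splice_site	LP	de_novo	TRUE
22	F22	3	46,XY	Male	Severe-PGD	severe_DSD	c.71A>T	p.His24Leu	het	missense	LP	unresolved	TRUE
23	F23	3	46,XY	Female	Opposite sex-PGD	opposite_sex_DSD	c.151G>T	p.Glu51*	het	stop_gained	P	unresolved	TRUE
24	F24	3	46,XY	Female	Severe-PGD	severe_DSD	c.1379A>G	p.Gln460Arg	het	missense	VUS	unresolved	TRUE
25	F25	3	46,XY	Male	Severe-Gonadal regression	severe_DSD	c.271G>A	p.Gly91Ser	het	missense	LP	unresolved	TRUE
27	F27	3	46,XY	Male	Opposite sex-CGD	opposite_sex_DSD	c.1183_1185delGAG	p.Glu395del	het	inframe_indel	LP	unresolved	TRUE
28	F28	3	46,XY	Male	Severe-PGD	severe_DSD	c.58G>C	p.Val20Leu	het	missense	LP	unresolved	TRUE
29	F29	3	46,XY	Female	Opposite sex-PGD	opposite_sex_DSD	c.268G>C	p.Gly90Arg	het	missense	VUS	unresolved	TRUE
30	F30	3	46,XY	Female	Opposite sex-PGD	opposite_sex_DSD	c.614_615insC	p.Gln206Thrfs*20	het	frameshift	missing	unresolved	TRUE
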