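case_id	gene	hgvs_c	hgvs_p	zygosity	score	effect_class	acmg_varsome	acmg_franklin	cadd	gnomad_af	source_table
7	COL9A3	c.43_48del	p.(Leu15_Leu16del)	het	ND	missing	VUS	VUS	8.77	5.63e-05	2
8	DHX37	c.904G>A	p.(Gly302Ser)	het	ND	missing	VUS	VUS	24.9	3.94e-05	2
9	PKD1	c.6598C>T	p.(Arg2200Cys)	het	0.9950	true_digenic	B	VUS	22.9		3
9	CITED2	c.117_119del	p.(His39del)	het	0.9800	true_digenic	B	LB	22.0		3
9	PDGFRA	c.1285G>A	p.(Gly429Arg)	het	0.9775	true_digenic	LB	VUS	22.4		3
9	FLNB	c.4233C>G	p.(Phe1411Leu)	het	0.9375	true_digenic	B	LB	21		3
9	FLNB	c.6017A>G	p.(Lys2006Arg)	het	0.9375	true_digenic	B	LB	21		3
9	TBCE	c.214C>T	p.(Pro72Ser)	het	0.8550	true_digenic	B	B	23.2		3
10	ZFPM2	c.292G>A	p.(Asp98Asn)	het	0.9975	missing	B	B	23.9		3
10	CCDC59	c.499A>G	p.(Thr167Ala)	het	0.8075	missing	VUS	VUS	25.3		3
11	GLI3	c.2179G>A	p.(Gly727Arg)	het	0.9850	missing	B	VUS	25.5		3
11	KANK1	c.1322C>T	p.(Thr441Ile)	het	0.8425	missing	VUS	VUS	24.3		3
12	GLI3	c.2179G>A	p.(Gly727Arg)	het	0.9850	true_digenic	B	VUS	25.5		3
12	APC	c.7514G>A	p.(Arg2505Gln)	het	0.9600	true_digenic	B	B	23.8		3
12	PKD1	c.12436G>A	p.(Val4146Ile)	het	0.9950	true_digenic	B	VUS	23.3		3
12	SYNM	c.361C>A	p.(Gln121Lys)	het	0.7025	monogenic_modifier	LB	VUS	19.38		3
12	SYNM	c.368C>T	p.(Ala123Val)	het	0.7025	monogenic_modifier	LB	VUS	20.5		3
13	GLI3	c.2179G>A	p.(Gly727Arg)	het	0.9850	missing	B	VUS	25.5		3
13	CBX2	c.849G>T	p.(Lys283Asn)	het	0.9550	missing	B	B	20.7		3
14	SPRY4	c.55C>G	p.(Gln19Glu)	het	0.9300	missing	VUS	VUS	24.6		3
14	TBCE	c.214C>T	p.(Pro72Ser)	het	0.8600	missing	B	B	23.2		3
15	INO80	c.3842G>A	p.(Arg1281Gln)	het	0.9450	missing	B	VUS	27.6		3
15	FLNB	c.6956T>C	p.(Ile2319Thr)	het	0.9400	missing	B	B	28.0		3
15	SPRY4	c.653C>A	p.(Ser218Tyr)	het	0.9275	missing	VUS	VUS	27.8		3
15	MKKS	c.724G>T	p.(Ala242Ser)	het	0.9175	missing	LB	VUS	24.9		3
15	FDXR	c.815C>T	p.(Pro272Leu)	het	0.8525	missing	VUS	VUS	27.6		3
16	FLNB	c.6956T>C	p.(Ile2319Thr)	het	0.9475	missing	B	B	28.0		3
16	KAT6B	c.5252C>A	p.(Pro1751His)	het	0.9650	missing	VUS	VUS	24.4		3
16	MYO7A	c.2293C>A	p.(Leu765Met)	het	0.9000	missing	B	LB	23.2		3
16	PKD1	c.2081C>T	p.(Pro694Leu)	het	0.9950	missing	LB	VUS	25.4		3
17	SEMA6D	c.626G>A	p.(Arg209His)	het	0.9050	missing	LB	VUS	32		3
17	PDGFRA	c.1285G>A	p.(Gly429Arg)	het	0.9750	missing	LB	VUS	16.3		3
17	ZNF462	c.4093G>A	p.(Glu1365Lys)	het	0.9825	missing	B	VUS	25.1		3
18	DKK1	c.470G>T	p.Ser157Ile	het	0.9400	missing	B	LB	21.7		3
18	AXIN1	c.1485C>G	p.(Asp495Glu)	het	0.9275	missing	B	VUS	17.2		3
19	SFRP1	c.539C>T	p.(Pro180Leu)	het	0.9725	missing	B	VUS	26.8		3
19	COL1A1	c.1559A>G	p.(Lys520Arg)	het	0.8975	missing	VUS	VUS	23.1		3
20	LRP6	c.4402G>A	p.(Ala1468Thr)	het	0.9900	missing	B	VUS	27.4		3
20	ETNK2	c.920A>C	p.(Gln307Pro)	het	0.8625	missing	VUS	VUS	22.9		3
21	GLI2	c.803C>T	p.(Ala268Val)	het	0.9725	missing	B	B	25.0		3
21	CDH23	c.5831T>C	p.(Leu1944Ser)	het	0.9450	missing	B	VUS	22.6		3
21	LGR5	c.1148A>G	p.(His383Arg)	het	0.9425	missing	B	LB	22.3		3
21	GATA5	c.232G>A	p.Gly78Ser	het	0.8675	missing	B	LB	15.44		3
21	PPARGC1B	c.1088C>T	p.(Thr363Met)	het	0.8625	missing	B	B	17.2		3
21	PPARGC1B	c.1499C>T	p.(Ser500Leu)	het	0.8625	missing	B	B	10.03		3
22	MAPK14	c.1028A>G	p.(Asp343Gly)	het	0.9850	missing	B	LB	23.4		3
22	PLXNB1	c.1360A>C	p.(Ser454Arg)	het	0.8850	missing	B	VUS	25.7		3
22	PTCH1	c.4324C>T	p.(Leu277Met)	het	0.8625	missing	B	LB	20.2		3
22	HHAT	c.829C>A	p.(Leu277Met)	het	0.8600	missing	VUS	VUS	23.8		3
22	HHAT	c.1130A>G	p.(Tyr377Cys)	het	0.8600	missing	VUS	VUS	23.0		3
23	SRA1	c.413G>A	p.(Gly138Glu)	het	0.9625	missing	B	LB	19.2		3
23	MYO7A	c.1868G>A	p.(Arg623His)	het	0.9225	missing	B	B	26.8		3
23	SRCAP	c.4499C>T	p.(Pro1500Leu)	het	0.9100	missing	B	VUS	22.1		3
23	SRCAP	c.4603C>G	p.(Pro1535Ala)	het	0.9100	missing	B	B	17.8		3
24	TBX2	c.1139C>G	p.(Pro380Arg)	het	0.8875	missing	VUS	VUS	24.7		3
24	FLNB	c.2195A>G	p.(Tyr732Cys)	het	0.6900	missing	VUS	VUS	23.8		3
25	NOS1	c.335C>T	p.(Thr112Ile)	het	0.9850	missing	B	VUS	23.2		3
25	FLNB	c.6017A>G	p.(Lys2006Arg)	het	0.8975	missing	B	B	21.0		3
25	AKR1C3	c.548A>T	p.Lys183Met	het	0.8875	missing	B	VUS	25.6		3
25	DHRS7	c.431G>A	p.(Arg144His)	het	0.7175	missing	VUS	VUS	26.7		3
25	KAT6B	c.2134G>T	p.(Gly712Trp)	het	0.9700	missing	B	VUS	28.0		3
25	RXFP2	c.1594C>G	p.(Arg532Gly)	het	0.8675	missing	B	VUS	20.4		3
27	ZFPM2	c.1632G>A	p.(Met544Ile)	het	0.9900	missing	LB	B	20.5		3
28	CDH23	c.1096G>A	p.(Ala366Thr)	het	0.9475	missing	B	B	25.6		3
28	NR1H2	c.515_516insCAA	p.(Arg171_Lys172insAsn)	het	ND	missing	VUS	VUS	ND		3
29	ZFPM2	c.302G>A	p.(Gly101Glu)	het	0.9975	missing	B	VUS	25.2		3
29	SRA1	c.94C>G	p.(Gln32Glu)	het	0.9825	missing	B	B	26.7		3
29	FBLN2	c.385G>A	p.(Asp129Asn)	het	0.8675	missing	LB	VUS	29.1		3
30	GLI2	c.4332G>A	p.(Met1444Ile)	het	0.9400	missing	B	B	15.95		3
30	GLI2	c.4333C>T	p.(Leu1445Phe)	het	0.9400	missing	B	B	22.4		3
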