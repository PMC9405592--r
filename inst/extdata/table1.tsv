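gencode_id	gencode_name	missense	cis_eqtl	kegg	ppi	ko_mice	total_score
ENSG00000113520	IL4	0	1	1	1	1	4
ENSG00000115604	IL18R1	0	1	1	1	1	4
ENSG00000160712	IL6R	1	1	0	1	1	4
ENSG00000166888	STAT6	0	1	1	1	1	4
ENSG00000166949	SMAD3	0	1	1	1	1	4
ENSG00000169194	IL13	1	0	1	1	1	4
ENSG00000174125	TLR1	1	1	0	1	1	4
ENSG00000020633	RUNX3	0	1	0	1	1	3
ENSG00000069667	RORA	0	0	1	1	1	3
ENSG00000107485	GATA3	0	0	1	1	1	3
ENSG00000109471	IL2	0	0	1	1	1	3
ENSG00000113525	IL5	0	0	1	1	1	3
ENSG00000115602	IL1RL1	1	0	0	1	1	3
ENSG00000117586	TNFSF4	0	1	0	1	1	3
ENSG00000125347	IRF1	0	1	0	1	1	3
ENSG00000134215	VAV3	0	1	0	1	1	3
ENSG00000138684	IL21	0	0	1	1	1	3
ENSG00000141736	ERBB2	1	0	0	1	1	3
ENSG00000158869	FCER1G	0	1	0	1	1	3
ENSG00000161405	IKZF3	0	1	0	1	1	3
ENSG00000179344	HLA-DQB1	0	1	1	0	1	3
ENSG00000204252	HLA-DOA	0	0	1	1	1	3
ENSG00000204287	HLA-DRA	1	1	1	0	0	3
ENSG00000231389	HLA-DPA1	0	1	1	1	0	3
ENSG00000073605	GSDMB	1	1	0	0	0	2
ENSG00000074047	GLI2	0	0	0	1	1	2
ENSG00000079112	CDH17	0	0	0	1	1	2
ENSG00000087086	FTL	0	0	0	1	1	2
ENSG00000087088	BAX	0	0	0	1	1	2
ENSG00000100385	IL2RB	0	1	0	0	1	2
ENSG00000100902	PSMA6	0	1	0	1	0	2
ENSG00000106571	GLI3	0	0	0	1	1	2
ENSG00000107957	SH3PXD2A	1	0	0	0	1	2
ENSG00000111145	ELK3	1	0	0		1	2
ENSG00000111335	OAS2	1	1	0		0	2
ENSG00000112130	RNF8	0	0	0	1	1	2
ENSG00000112486	CCR6	0	0	0	1	1	2
ENSG00000113522	RAD50	0	0	0	1	1	2
ENSG00000120903	CHRNA2	0	1	0	0	1	2
ENSG00000124107	SLPI	0	0	0	1	1	2
ENSG00000131507	NDFIP1	0	0	0	1	1	2
ENSG00000134460	IL2RA	0	0	0	1	1	2
ENSG00000134470	IL15RA	0	1	0	0	1	2
ENSG00000135905	DOCK10	0	0	0	1	1	2
ENSG00000137033	IL33	0	0	0	1	1	2
ENSG00000142556	ZNF614	1	1	0	0	0	2
ENSG00000143631	FLG	1	0	0	0	1	2
ENSG00000145777	TSLP	0	0	0	1	1	2
ENSG00000162104	ADCY9	0	1	0	0	1	2
ENSG00000163485	ADORA1	0	1	0	0	1	2
ENSG00000165280	VCP	0	0	0	1	1	2
ENSG00000167914	GSDMA	1	1	0	0	0	2
ENSG00000171132	PRKCE	0	0	0	1	1	2
ENSG00000171608	PIK3CD	0	0	0	1	1	2
ENSG00000172057	ORMDL3	0	1	0	1	0	2
ENSG00000174130	TLR6	0	0	0	1	1	2
ENSG00000179588	ZFPM1	0	0	0	1	1	2
ENSG00000180902	D2HGDH	1	1	0	0	0	2
ENSG00000186265	BTLA	0	0	0	1	1	2
ENSG00000186716	BCR	0	1	0	1	0	2
ENSG00000196735	HLA-DQA1	0	1	1	0	0	2
ENSG00000197746	PSAP	0	0	0	1	1	2
ENSG00000198821	CD247	0	1	0	0	1	2
ENSG00000204681	GABBR1	1	0	0	0	1	2
ENSG00000215182	MUC5AC	1	0	0	0	1	2
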