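subject	evidence_class	chrom	pos	ref	alt	read_depth	variation_type	cytoband	gene_region	gene	protein_variant	genotype	origin
WH	Novel functionally damaging	4	1808286	G	A	55	SNV	p16.3	Exonic	FGFR3	p.V682I; p.V684I; p.V570I	Het	Somatic
WH	Novel functionally damaging	10	49634537	A	C	45	SNV	q11.22	Exonic	MAPK8	p.E329A	Het	Somatic
WH	Novel functionally damaging	15	39884882	G	T	68	SNV	q14	Exonic	THBS1	p.Q882H	Het	Germline
WH	Novel functionally damaging	20	41420019	T	C	108	SNV	q12	Exonic	PTPRT	p.H101R	Het	Germline
WH	COSMIC	10	51568378	T	G	133	SNV	q11.23	Intronic; Exonic	NCOA4	p.F8V	Hom	Somatic
WH	COSMIC	17	7577538	C	T	111	SNV	p13.1	Exonic	TP53	p.R209Q; p.R116Q; p.R248Q	Het	Somatic
WH	COSMIC	3	47125385	G	A	29	SNV	p21.31	Exonic	SETD2	p.P1962L	Het	Germline
WH	COSMIC	3	142178144	C	T	104	SNV	q23	Exonic	ATR	p.R2425Q	Het	Germline
WH	COSMIC	3	142281612	A	G	119	SNV	q23	Exonic	ATR	p.M211T	Het	Germline
WH	COSMIC	5	35861068	T	C	163	SNV	p13.2	Exonic	IL7R	p.I66T	Het	Germline
WH	COSMIC	5	35871190	G	A	152	SNV	p13.2	Exonic	IL7R	p.V138I	Het	Germline
WH	COSMIC	6	51910905	T	C	160	SNV	p12.2	Exonic	PKHD1	p.N830S	Het	Germline
WH	COSMIC	6	152665261	C	A	100	SNV	q25.2	Exonic	SYNE1	p.E3989D; p.E4060D	Het	Germline
WH	COSMIC	7	151882672	C	A	79	SNV	q36.1	Exonic	MLL3	p.A1685S	Het	Germline
WH	COSMIC	7	151962265	C	T	855	SNV	q36.1	Exonic	MLL3	p.D348N	Het	Germline
WH	COSMIC	9	8518052	G	C	103	SNV	p24.1	Exonic	PTPRD	p.Q447E; p.Q444E; p.Q441E; p.Q437E	Het	Germline
WH	COSMIC	9	21968199	C	G	57	SNV	p21.3	3'UTR	CDKN2A		Hom	Germline
WH	COSMIC	10	76781908	G	GAGGATGAAGAGGAGGAAGAAGAG	126	Insertion	q22.2	Exonic	KAT6B	p.914_915insEDEEEEEE; p.805_806insEDEEEEEE; p.1097_1098insEDEEEEEE	Het	Germline
WH	COSMIC	15	39880822	A	G	204	SNV	q14	Exonic	THBS1	p.T523A	Het	Germline
WH	COSMIC	17	7579472	G	C	96	SNV	p13.1	Promoter; Exonic	TP53	p.P72R; p.P33R	Het	Germline
WoH	COSMIC	6	152665261	C	A	33	SNV	q25.2	Exonic	SYNE1	p.E3989D; p.E4060D	Hom	Somatic
WoH	COSMIC	10	51568378	T	G	97	SNV	q11.23	Intronic; Exonic	NCOA4	p.F8V	Hom	Somatic
WoH	COSMIC	10	96540410	G	A	103	SNV	q23.33	Exonic	CYP2C19	p.W212*	Het	Somatic
WoH	COSMIC	17	78302157	C	A	53	SNV	q25.3	Exonic	RNF213	p.Q1133K	Hom	Somatic
WoH	COSMIC	17	78319136	G	A	103	SNV	q25.3	Exonic	RNF213	p.S2334N	Hom	Somatic
WoH	COSMIC	3	47125385	G	A	71	SNV	p21.31	Exonic	SETD2	p.P1962L	Het	Germline
WoH	COSMIC	3	142281612	A	G	171	SNV	q23	Exonic	ATR	p.M211T	Het	Germline
WoH	COSMIC	4	55593464	A	C	42	SNV	q12	Exonic	KIT	p.M541L; p.M537L	Het	Germline
WoH	COSMIC	9	21968199	C	G	65	SNV	p21.3	3'UTR	CDKN2A		Hom	Germline
WoH	COSMIC	10	76781908	G	GAGGATGAAGAGGAGGAAGAAGAG	69	Insertion	q22.2	Exonic	KAT6B	p.914_915insEDEEEEEE; p.805_806insEDEEEEEE; p.1097_1098insEDEEEEEE	Het	Germline
WoH	COSMIC	11	108175462	G	A	111	SNV	q22.3	Exonic	ATM	p.D1853N	Het	Germline
WoH	COSMIC	17	7579472	G	C	60	SNV	p13.1	Promoter; Exonic	TP53	p.P72R; p.P33R	Het	Germline
WoH	Novel functionally damaging	4	1808286	G	A	34	SNV	p16.3	Exonic	FGFR3	p.V682I; p.V684I; p.V570I	Het	Somatic
WoH	Novel functionally damaging	3	128202753	G	A	46	SNV	q21.3	Exonic	GATA2	p.H323Y	Het	Germline
WoH	Novel functionally damaging	6	56325048	G	A	40	SNV	p12.1	Exonic	DST	p.T5045M	Het	Germline
WoH	Novel functionally damaging	6	152638007	G	A	42	SNV	q25.2	Exonic	SYNE1	p.R5563W; p.R5492W	Het	Germline
WoH	Novel functionally damaging	10	43615078	G	T	72	SNV	q11.21	Exonic	RET	p.G831V	Het	Germline
WoH	Novel functionally damaging	15	39884882	G	T	28	SNV	q14	Exonic	THBS1	p.Q882H	Het	Germline
WoH	Novel functionally damaging	20	41420019	T	C	55	SNV	q12	Exonic	PTPRT	p.H101R	Het	Germline
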