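rank	degree_name	degree	betweenness_name	betweenness	closeness_name	closeness
1	TP53	66	TP53	0.12965202	TP53	0.75193798
2	AKT1	49	HSP90AA1	0.07551998	AKT1	0.65986395
3	EGF	47	HSPA4	0.06902023	EGF	0.65100671
4	PCNA	47	IL6	0.06776382	VEGFA	0.64666667
5	JUN	46	AKT1	0.04867524	PCNA	0.64666667
6	VEGFA	44	VEGFA	0.04389668	JUN	0.64666667
7	ESR1	42	PCNA	0.03662677	IL6	0.63815789
8	IL6	42	EGF	0.034913	ESR1	0.62987013
9	CDK1	41	ESR1	0.02917485	BCL2	0.62580645
10	BCL2	41	JUN	0.02822688	EGFR	0.62179487
11	HSP90AA1	40	TNF	0.02701286	HSP90AA1	0.61783439
12	CDK2	40	CDK1	0.02175952	TNF	0.61783439
13	CCND1	40	PTGS2	0.02156667	CDKN1A	0.61006289
14	EGFR	40	PPARG	0.02083383	FOS	0.61006289
15	TNF	39	AKR1C3	0.02075601	PIK3CG	0.61006289
16	CDKN1A	38	ALOX5	0.02061856	HSPA4	0.60625
17	PIK3CG	37	AR	0.01863776	CDK2	0.60625
18	FOS	37	CDK2	0.01810019	AR	0.60248447
19	HSPA4	37	NOS3	0.017597	MAPK8	0.60248447
20	MAPK8	35	EGFR	0.01749873	PTGS2	0.59876543
21	AR	34	CCND1	0.01665403	CDK1	0.59509202
22	CCNB1	33	MAPK8	0.01587777	CCND1	0.59509202
23	NOS3	33	CDKN1A	0.01556023	NOS3	0.59146341
24	PTGS2	33	BCL2	0.0151564	MMP2	0.58083832
25	CHEK1	30	FOS	0.01323593	MAPK14	0.58083832
26	CDKN1B	30	MMP2	0.0125	CALM2	0.57058824
27	MMP2	30	PGR	0.00972	CALM1	0.57058824
28	MAPK14	30	CDKN1B	0.00965	CDKN1B	0.56725146
29	CCNA2	29	PIK3CG	0.00952	MDM2	0.56725146
30	MDM2	29	CALM2	0.00918	KDR	0.55747126
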