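snp_id	chrom	pos	allele1	allele2	p_nominal	p_bonferroni_printed	p_source	nearby_gene
rs75968099	3	36858583	T	C	2.03e-05	0.0022	1.05e-13	TRANK1
rs2535627	3	52845105	T	C	4.68e-05	0.0052	4.26e-11	ITIH3-ITIH4
rs6704641	2	200164252	A	G	0.0030	0.3331	8.33e-09	SATB2
rs140505938	1	150031490	T	C	0.0032	0.3597	4.49e-10	VPS45
rs7893279	10	18745105	T	G	0.0043	0.4770	1.97e-12	CACNB2
rs6704768	2	233592501	A	G	0.0063	0.6991	2.32e-12	GIGYF2
rs12704290	7	86427626	A	G	0.0075	0.8315	3.33e-10	GRM3
rs211829	7	110048893	T	C	0.0088	0.9778	3.71e-08	-
rs3735025	7	137074844	T	C	0.0098	1	3.28e-09	DGKI
rs324017	12	57487814	A	C	0.0098	1	2.13e-08	NAB2
rs2909457	2	162845855	A	G	0.0109	1	4.62e-08	SLC4A10-DPP4
rs9922678	16	9946319	A	G	0.0120	1	1.28e-08	GRIN2A
rs950169	15	84706461	T	C	0.0181	1	1.62e-11	ADAMTSL3
rs55661361	11	124613957	A	G	0.0301	1	2.8e-12	NRGN
rs10043984	5	137712121	T	C	0.0307	1	1.09e-08	KDM3B
rs1498232	1	30433951	T	C	0.0323	1	2.86e-09	LOC101929406
rs6434928	2	198304577	A	G	0.0351	1	2.06e-11	SF3B1-COQ10B
rs2007044	12	2344960	A	G	0.0367	1	3.22e-18	CACNA1C
rs8044995	16	68189340	A	G	0.0380	1	1.51e-08	NFATC3
rs56205728	15	40567237	A	G	0.0387	1	4.18e-09	PAK6
rs2693698	14	99719219	A	G	0.0429	1	4.8e-09	BCL11B
rs832187	3	63833050	T	C	0.0465	1	1.43e-08	THOC7
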