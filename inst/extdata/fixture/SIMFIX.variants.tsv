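chrom	pos	ref	alt	gene	consequence	compartment	ref_depth	alt_depth
chr6	130265076	CCCG	C	GENE3615	inframe_indel	epidermis	67	56
chr9	83632337	G	T	GENE3418	missense	epidermis	57	56
chr12	110106021	AAA	A	GENE2896	frameshift	epidermis	72	55
chr21	149243671	G	GC	GENE1997	frameshift	epidermis	73	40
chr21	3042935	ATTCGATTTT	A	GENE4199	inframe_indel	epidermis	61	54
chr9	62156053	G	A	GENE0719	missense	epidermis	64	48
chr2	74861855	G	A	GENE3295	synonymous	epidermis	63	51
chr13	141581222	T	TTAT	GENE0057	inframe_indel	epidermis	81	46
chr21	1389481	A	G	GENE4580	missense	epidermis	136	0
chr19	101574975	A	G	GENE2169	missense	epidermis	109	0
chr8	49279899	C	A	GENE1394	missense	epidermis	138	0
chr11	209181306	G	A	GENE3346	synonymous	epidermis	114	0
chr8	185837992	G	C	GENE0214	synonymous	epidermis	123	0
chr8	52991811	C	A	GENE1378	missense	epidermis	145	0
chr1	53846577	A	G	GENE2051	utr3	epidermis	132	0
chr6	49921632	A	C	GENE2647	missense	epidermis	150	0
chr1	88592540	CATAG	C	GENE1276	frameshift	epidermis	99	0
chr11	115294296	G	C	GENE3566	stop_gain	epidermis	115	0
chr18	116814664	T	C	GENE2336	missense	epidermis	99	0
chr1	75527578	C	T	GENE0049	missense	epidermis	115	0
chr7	239201	A	T	GENE4313	missense	epidermis	100	0
chr22	74879403	A	G	GENE4059	utr3	epidermis	124	0
chr21	182719344	A	G	GENE2324	synonymous	epidermis	129	0
chr12	104500854	G	C	GENE2581	missense	epidermis	114	0
chr6	4696421	C	CACTG	GENE2003	frameshift	epidermis	82	56
chr22	139092686	A	G	GENE4816	missense	epidermis	74	47
chr3	207969006	T	C	GENE2533	synonymous	epidermis	64	57
chr20	68865741	A	G	GENE2896	other	epidermis	74	45
chr12	66673363	A	G	GENE0158	missense	epidermis	138	0
chr18	142369037	C	T	GENE0506	missense	epidermis	116	0
chr2	35829228	T	G	GENE2259	missense	epidermis	132	0
chr2	47583841	ATCGACT	A	GENE4845	inframe_indel	epidermis	122	0
chr19	67980951	T	C	GENE3279	missense	epidermis	133	0
chr1	112858835	CCAT	C	GENE3945	inframe_indel	epidermis	136	0
chr13	61124287	C	G	GENE4272	missense	epidermis	137	0
chr22	4512537	C	G	GENE2705	missense	epidermis	136	0
chr18	38136939	A	ATTGCCG	GENE1542	inframe_indel	epidermis	112	0
chr12	204006756	G	C	GENE4302	synonymous	epidermis	123	0
chr3	5742979	C	CCCAG	GENE0811	frameshift	epidermis	108	0
chr12	183983684	G	A	GENE1054	missense	epidermis	125	0
chr1	44414810	T	G	GENE1021	missense	epidermis	125	0
chr4	180562386	G	T	GENE0545	missense	epidermis	130	0
chr17	214353431	C	A	GENE3943	synonymous	epidermis	120	0
chr3	27168619	A	C	GENE3568	missense	epidermis	111	0
chr7	43895065	C	A	NCOR1	missense	epidermis	102	0
chr2	97189024	CCAAATA	C	GENE3706	inframe_indel	epidermis	111	0
chr18	204609370	A	G	GENE2253	utr3	epidermis	122	0
chr5	62691138	G	A	GENE3372	missense	epidermis	124	0
chr10	18867453	C	A	GENE0625	utr3	epidermis	140	0
chr8	24561134	A	T	GENE4740	synonymous	epidermis	128	0
chr8	145992559	C	A	GENE3315	missense	epidermis	110	2
chr20	203636183	C	A	GENE0348	missense	epidermis	107	3
chr20	160238067	T	G	GENE0881	missense	epidermis	148	1
chr16	145538192	G	C	CDK12	synonymous	epidermis	85	27
chr8	207787892	G	T	GENE2430	synonymous	epidermis	92	21
chr17	184033238	G	C	GENE0645	missense	epidermis	117	16
chr5	77466625	T	G	GENE0231	missense	epidermis	93	19
chr12	114607428	C	A	GENE0023	missense	epidermis	117	11
chr6	54993178	C	A	GENE4379	other	epidermis	109	12
chr7	168461523	C	T	GENE2399	missense	epidermis	99	19
chr20	13266409	A	T	GENE3686	missense	epidermis	103	12
chr6	130265076	CCCG	C	GENE3615	inframe_indel	dermis	76	21
chr9	83632337	G	T	GENE3418	missense	dermis	94	30
chr12	110106021	AAA	A	GENE2896	frameshift	dermis	78	30
chr21	149243671	G	GC	GENE1997	frameshift	dermis	77	34
chr21	3042935	ATTCGATTTT	A	GENE4199	inframe_indel	dermis	100	29
chr9	62156053	G	A	GENE0719	missense	dermis	81	24
chr2	74861855	G	A	GENE3295	synonymous	dermis	85	35
chr13	141581222	T	TTAT	GENE0057	inframe_indel	dermis	91	28
chr21	1389481	A	G	GENE4580	missense	dermis	95	36
chr19	101574975	A	G	GENE2169	missense	dermis	90	32
chr8	49279899	C	A	GENE1394	missense	dermis	86	42
chr11	209181306	G	A	GENE3346	synonymous	dermis	93	34
chr8	185837992	G	C	GENE0214	synonymous	dermis	96	36
chr8	52991811	C	A	GENE1378	missense	dermis	77	23
chr1	53846577	A	G	GENE2051	utr3	dermis	95	34
chr6	49921632	A	C	GENE2647	missense	dermis	69	32
chr1	88592540	CATAG	C	GENE1276	frameshift	dermis	99	29
chr11	115294296	G	C	GENE3566	stop_gain	dermis	91	34
chr18	116814664	T	C	GENE2336	missense	dermis	98	41
chr1	75527578	C	T	GENE0049	missense	dermis	93	30
chr7	239201	A	T	GENE4313	missense	dermis	77	40
chr22	74879403	A	G	GENE4059	utr3	dermis	84	38
chr21	182719344	A	G	GENE2324	synonymous	dermis	99	26
chr12	104500854	G	C	GENE2581	missense	dermis	97	27
chr6	4696421	C	CACTG	GENE2003	frameshift	dermis	111	0
chr22	139092686	A	G	GENE4816	missense	dermis	97	0
chr3	207969006	T	C	GENE2533	synonymous	dermis	134	0
chr20	68865741	A	G	GENE2896	other	dermis	120	0
chr12	66673363	A	G	GENE0158	missense	dermis	142	0
chr18	142369037	C	T	GENE0506	missense	dermis	125	0
chr2	35829228	T	G	GENE2259	missense	dermis	135	1
chr2	47583841	ATCGACT	A	GENE4845	inframe_indel	dermis	134	0
chr19	67980951	T	C	GENE3279	missense	dermis	134	3
chr1	112858835	CCAT	C	GENE3945	inframe_indel	dermis	123	12
chr13	61124287	C	G	GENE4272	missense	dermis	119	6
chr22	4512537	C	G	GENE2705	missense	dermis	96	6
chr18	38136939	A	ATTGCCG	GENE1542	inframe_indel	dermis	113	12
chr12	204006756	G	C	GENE4302	synonymous	dermis	109	9
chr3	5742979	C	CCCAG	GENE0811	frameshift	dermis	100	16
chr12	183983684	G	A	GENE1054	missense	dermis	104	13
chr1	44414810	T	G	GENE1021	missense	dermis	96	8
chr4	180562386	G	T	GENE0545	missense	dermis	89	12
chr17	214353431	C	A	GENE3943	synonymous	dermis	98	13
chr3	27168619	A	C	GENE3568	missense	dermis	108	20
chr7	43895065	C	A	NCOR1	missense	dermis	106	22
chr2	97189024	CCAAATA	C	GENE3706	inframe_indel	dermis	94	7
chr18	204609370	A	G	GENE2253	utr3	dermis	93	22
chr5	62691138	G	A	GENE3372	missense	dermis	110	22
chr10	18867453	C	A	GENE0625	utr3	dermis	100	15
chr8	24561134	A	T	GENE4740	synonymous	dermis	96	15
chr8	145992559	C	A	GENE3315	missense	dermis	127	0
chr20	203636183	C	A	GENE0348	missense	dermis	111	0
chr20	160238067	T	G	GENE0881	missense	dermis	133	0
chr16	145538192	G	C	CDK12	synonymous	dermis	113	0
chr8	207787892	G	T	GENE2430	synonymous	dermis	114	0
chr17	184033238	G	C	GENE0645	missense	dermis	127	0
chr5	77466625	T	G	GENE0231	missense	dermis	119	0
chr12	114607428	C	A	GENE0023	missense	dermis	113	0
chr6	54993178	C	A	GENE4379	other	dermis	123	0
chr7	168461523	C	T	GENE2399	missense	dermis	115	0
chr20	13266409	A	T	GENE3686	missense	dermis	128	0
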