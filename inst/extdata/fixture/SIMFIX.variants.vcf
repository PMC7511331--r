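##fileformat=VCFv4.2
##source=skinclones
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	dermis	epidermis
chr1	44414810	.	T	G	.	PASS	GENE=GENE1021;CSQ=missense	AD	96,8	125,0
chr1	53846577	.	A	G	.	PASS	GENE=GENE2051;CSQ=utr3	AD	95,34	132,0
chr1	75527578	.	C	T	.	PASS	GENE=GENE0049;CSQ=missense	AD	93,30	115,0
chr1	88592540	.	CATAG	C	.	PASS	GENE=GENE1276;CSQ=frameshift	AD	99,29	99,0
chr1	112858835	.	CCAT	C	.	PASS	GENE=GENE3945;CSQ=inframe_indel	AD	123,12	136,0
chr2	35829228	.	T	G	.	PASS	GENE=GENE2259;CSQ=missense	AD	135,1	132,0
chr2	47583841	.	ATCGACT	A	.	PASS	GENE=GENE4845;CSQ=inframe_indel	AD	134,0	122,0
chr2	74861855	.	G	A	.	PASS	GENE=GENE3295;CSQ=synonymous	AD	85,35	63,51
chr2	97189024	.	CCAAATA	C	.	PASS	GENE=GENE3706;CSQ=inframe_indel	AD	94,7	111,0
chr3	5742979	.	C	CCCAG	.	PASS	GENE=GENE0811;CSQ=frameshift	AD	100,16	108,0
chr3	27168619	.	A	C	.	PASS	GENE=GENE3568;CSQ=missense	AD	108,20	111,0
chr3	207969006	.	T	C	.	PASS	GENE=GENE2533;CSQ=synonymous	AD	134,0	64,57
chr4	180562386	.	G	T	.	PASS	GENE=GENE0545;CSQ=missense	AD	89,12	130,0
chr5	62691138	.	G	A	.	PASS	GENE=GENE3372;CSQ=missense	AD	110,22	124,0
chr5	77466625	.	T	G	.	PASS	GENE=GENE0231;CSQ=missense	AD	119,0	93,19
chr6	4696421	.	C	CACTG	.	PASS	GENE=GENE2003;CSQ=frameshift	AD	111,0	82,56
chr6	49921632	.	A	C	.	PASS	GENE=GENE2647;CSQ=missense	AD	69,32	150,0
chr6	54993178	.	C	A	.	PASS	GENE=GENE4379;CSQ=other	AD	123,0	109,12
chr6	130265076	.	CCCG	C	.	PASS	GENE=GENE3615;CSQ=inframe_indel	AD	76,21	67,56
chr7	239201	.	A	T	.	PASS	GENE=GENE4313;CSQ=missense	AD	77,40	100,0
chr7	43895065	.	C	A	.	PASS	GENE=NCOR1;CSQ=missense	AD	106,22	102,0
chr7	168461523	.	C	T	.	PASS	GENE=GENE2399;CSQ=missense	AD	115,0	99,19
chr8	24561134	.	A	T	.	PASS	GENE=GENE4740;CSQ=synonymous	AD	96,15	128,0
chr8	49279899	.	C	A	.	PASS	GENE=GENE1394;CSQ=missense	AD	86,42	138,0
chr8	52991811	.	C	A	.	PASS	GENE=GENE1378;CSQ=missense	AD	77,23	145,0
chr8	145992559	.	C	A	.	PASS	GENE=GENE3315;CSQ=missense	AD	127,0	110,2
chr8	185837992	.	G	C	.	PASS	GENE=GENE0214;CSQ=synonymous	AD	96,36	123,0
chr8	207787892	.	G	T	.	PASS	GENE=GENE2430;CSQ=synonymous	AD	114,0	92,21
chr9	62156053	.	G	A	.	PASS	GENE=GENE0719;CSQ=missense	AD	81,24	64,48
chr9	83632337	.	G	T	.	PASS	GENE=GENE3418;CSQ=missense	AD	94,30	57,56
chr10	18867453	.	C	A	.	PASS	GENE=GENE0625;CSQ=utr3	AD	100,15	140,0
chr11	115294296	.	G	C	.	PASS	GENE=GENE3566;CSQ=stop_gain	AD	91,34	115,0
chr11	209181306	.	G	A	.	PASS	GENE=GENE3346;CSQ=synonymous	AD	93,34	114,0
chr12	66673363	.	A	G	.	PASS	GENE=GENE0158;CSQ=missense	AD	142,0	138,0
chr12	104500854	.	G	C	.	PASS	GENE=GENE2581;CSQ=missense	AD	97,27	114,0
chr12	110106021	.	AAA	A	.	PASS	GENE=GENE2896;CSQ=frameshift	AD	78,30	72,55
chr12	114607428	.	C	A	.	PASS	GENE=GENE0023;CSQ=missense	AD	113,0	117,11
chr12	183983684	.	G	A	.	PASS	GENE=GENE1054;CSQ=missense	AD	104,13	125,0
chr12	204006756	.	G	C	.	PASS	GENE=GENE4302;CSQ=synonymous	AD	109,9	123,0
chr13	61124287	.	C	G	.	PASS	GENE=GENE4272;CSQ=missense	AD	119,6	137,0
chr13	141581222	.	T	TTAT	.	PASS	GENE=GENE0057;CSQ=inframe_indel	AD	91,28	81,46
chr16	145538192	.	G	C	.	PASS	GENE=CDK12;CSQ=synonymous	AD	113,0	85,27
chr17	184033238	.	G	C	.	PASS	GENE=GENE0645;CSQ=missense	AD	127,0	117,16
chr17	214353431	.	C	A	.	PASS	GENE=GENE3943;CSQ=synonymous	AD	98,13	120,0
chr18	38136939	.	A	ATTGCCG	.	PASS	GENE=GENE1542;CSQ=inframe_indel	AD	113,12	112,0
chr18	116814664	.	T	C	.	PASS	GENE=GENE2336;CSQ=missense	AD	98,41	99,0
chr18	142369037	.	C	T	.	PASS	GENE=GENE0506;CSQ=missense	AD	125,0	116,0
chr18	204609370	.	A	G	.	PASS	GENE=GENE2253;CSQ=utr3	AD	93,22	122,0
chr19	67980951	.	T	C	.	PASS	GENE=GENE3279;CSQ=missense	AD	134,3	133,0
chr19	101574975	.	A	G	.	PASS	GENE=GENE2169;CSQ=missense	AD	90,32	109,0
chr20	13266409	.	A	T	.	PASS	GENE=GENE3686;CSQ=missense	AD	128,0	103,12
chr20	68865741	.	A	G	.	PASS	GENE=GENE2896;CSQ=other	AD	120,0	74,45
chr20	160238067	.	T	G	.	PASS	GENE=GENE0881;CSQ=missense	AD	133,0	148,1
chr20	203636183	.	C	A	.	PASS	GENE=GENE0348;CSQ=missense	AD	111,0	107,3
chr21	1389481	.	A	G	.	PASS	GENE=GENE4580;CSQ=missense	AD	95,36	136,0
chr21	3042935	.	ATTCGATTTT	A	.	PASS	GENE=GENE4199;CSQ=inframe_indel	AD	100,29	61,54
chr21	149243671	.	G	GC	.	PASS	GENE=GENE1997;CSQ=frameshift	AD	77,34	73,40
chr21	182719344	.	A	G	.	PASS	GENE=GENE2324;CSQ=synonymous	AD	99,26	129,0
chr22	4512537	.	C	G	.	PASS	GENE=GENE2705;CSQ=missense	AD	96,6	136,0
chr22	74879403	.	A	G	.	PASS	GENE=GENE4059;CSQ=utr3	AD	84,38	124,0
chr22	139092686	.	A	G	.	PASS	GENE=GENE4816;CSQ=missense	AD	97,0	74,47
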