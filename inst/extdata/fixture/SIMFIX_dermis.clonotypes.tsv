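cloneId	readCount	readFraction	nSeqCDR3	aaSeqCDR3	allVHitsWithScore	allJHitsWithScore	isPartial
0	504	0.251874062968516	GTAAATCAATGCCACCGACACATCCCGGAAACCTTC	VNQCHRHIPETF	TRBV5-1*00(100)	TRBJ1-2*00(100)	FALSE
1	384	0.191904047976012	GCTCCAGCTAACATTGGCCGTAAC	APANIGRN	TRBV6-5*00(100)	TRBJ2-1*00(100)	FALSE
2	364	0.181909045477261	ATAAGGTCTTTATGCGGCGTAAAG	IRSLCGVK	TRBV9*00(100)	TRBJ1-3*00(100)	FALSE
3	219	0.109445277361319	AGCTGCTTCATGGCAACGGTACCTGGCCCTCGCCCCTTCATACCACTCGGA	SCFMATVPGPRPFIPLG	TRBV7-2*00(100)	TRBJ2-4*00(100)	FALSE
4	151	0.0754622688655672	TCCTCTCACAGATGCTTACATAGCACGATCGCAGACGTAGGTTTGCGAAAC	SSHRCLHSTIADVGLRN	TRBV2*00(100)	TRBJ1-6*00(100)	FALSE
5	86	0.0429785107446277	AGTTATAACGTCCCAGGTGGTTCTTTTGCGTAATGGTCCACAGATTCATCTGTTAAA	SYNVPGGSFA*WSTDSSVK	TRBV5-1*00(100)	TRBJ2-7*00(100)	FALSE
6	48	0.0239880059970015	CAAAGTGGGTGACAGGGCTTATAG	QSG*QGL*	TRBV28*00(100)	TRBJ2-5*00(100)	FALSE
7	47	0.023488255872064	TCCTTTGTACTGGTATCTTGGACG	SFVLVSWT	TRBV30*00(100)	TRBJ2-6*00(100)	FALSE
8	26	0.0129935032483758	TGTGTCGGTCAAGGGCCCCTTAATTTCATACTCAGCATTTATCATTTCGAATGGACA	CVGQGPLNFILSIYHFEWT	TRBV18*00(100)	TRBJ2-1*00(100)	FALSE
9	21	0.0104947526236882	GGATACGACCCGACCAGAGGTTGACAAAGGTGTCTCATTGCA	GYDPTRG*QRCLIA	TRBV13*00(100)	TRBJ1-3*00(100)	FALSE
10	20	0.00999500249875063	TAGACAACACGGAAGGAGAATTGCCCAGGGTCACCATTCGGTTCTCTATGGAGGCGA	*TTRKENCPGSPFGSLWRR	TRBV27*00(100)	TRBJ2-1*00(100)	FALSE
11	19	0.00949525237381309	CGTGTAACCCCCTTTATAAAGATCACC	RVTPFIKIT	TRBV19*00(100)	TRBJ2-4*00(100)	FALSE
12	13	0.00649675162418791	GTCGGAACATTGGCCGTAACCTCGGAGCAC	VGTLAVTSEH	TRBV7-9*00(100)	TRBJ2-1*00(100)	FALSE
13	11	0.00549725137431284	TAATGCACATCCATATGTGCTTAATTG	*CTSICA*L	TRBV7-9*00(100)	TRBJ2-7*00(100)	FALSE
14	9	0.00449775112443778	CGCTGCGAAGGAGAGTTGGAACTCACATTA	RCEGELELTL	TRBV29-1*00(100)	TRBJ2-5*00(100)	FALSE
15	7	0.00349825087456272	ACAAGAAGGATCTCACAGATCTGTCGCCCAACGGCTGTCGGGGAAAACCGTGGCGTC	TRRISQICRPTAVGENRGV	TRBV6-5*00(100)	TRBJ2-3*00(100)	FALSE
16	7	0.00349825087456272	ATGGCCATCACGAATATGTTGTTACGTGCACTAACGTCATCA	MAITNMLLRALTSS	TRBV28*00(100)	TRBJ2-4*00(100)	FALSE
17	6	0.00299850074962519	AGTACGTCAGTTCCAAAGATGCCACTCCCCTAAGTAATCAGCAAGGCATTTAAGTCC	STSVPKMPLP*VISKAFKS	TRBV7-2*00(100)	TRBJ2-6*00(100)	FALSE
18	6	0.00299850074962519	TCCACAAACTTGGGTGCATACACGAGCCATCATTACCTCCCCGCCCCT	STNLGAYTSHHYLPAP	TRBV28*00(100)	TRBJ2-6*00(100)	FALSE
19	5	0.00249875062468766	GATTGCCGTGCTTAGTTAGCGTCAACCTTCCTTTGTCGCTTTGAGCCG	DCRA*LASTFLCRFEP	TRBV18*00(100)	TRBJ2-5*00(100)	FALSE
20	4	0.00199900049975012	AATCAGAGGGGCGTGTAACGTCTAGAGATTTATAGTCAGGCCATAAGG	NQRGV*RLEIYSQAIR	TRBV19*00(100)	TRBJ2-3*00(100)	FALSE
21	4	0.00199900049975012	ACTAGGTTATATCTCACGAACCGTCATATCATA	TRLYLTNRHII	TRBV5-1*00(100)	TRBJ2-7*00(100)	FALSE
22	4	0.00199900049975012	ATGATGGGACTGCAACAGTGACACACCCTAGCACAGTCTCCAATATCGAGCTAA	MMGLQQ*HTLAQSPISS*	TRBV18*00(100)	TRBJ1-2*00(100)	FALSE
23	4	0.00199900049975012	CCGCGAGGCTAAAGGGTCTACAGTAGAGCGTAACGCAATCCCGGG	PRG*RVYSRA*RNPG	TRBV18*00(100)	TRBJ2-5*00(100)	FALSE
24	4	0.00199900049975012	CGCAGTGTCGGTTTCGTTCGTTTTGAAAGGTATACCGCAGTCCGCTAACACTTGGGC	RSVGFVRFERYTAVR*HLG	TRBV28*00(100)	TRBJ1-4*00(100)	FALSE
25	4	0.00199900049975012	GAGCGGCAACGGATCGTCAATCCTCGGTTCCCGTTTAAAGTCGAT	ERQRIVNPRFPFKVD	TRBV13*00(100)	TRBJ1-1*00(100)	FALSE
26	4	0.00199900049975012	TAAAGTGATCAAAAGATGCTCGATCGCATTCTACTACAGCCATTCCGAGTTCTAGCGCCT	*SDQKMLDRILLQPFRVLAP	TRBV30*00(100)	TRBJ2-6*00(100)	FALSE
27	3	0.00149925037481259	ATTCAGATCCCCCATAGCGAAAGTGACTATTTAGCCAGCCCGGTCGACACCGAATCGCTG	IQIPHSESDYLASPVDTESL	TRBV20-1*00(100)	TRBJ2-7*00(100)	FALSE
28	3	0.00149925037481259	CACTCGAATGAGCAATGATCCATGGCCCGT	HSNEQ*SMAR	TRBV29-1*00(100)	TRBJ1-3*00(100)	FALSE
29	2	0.000999500249875062	AACCCAACACGTCTGCTGGTATCATGAGTTGCTTTCGTGAATCTGGACGCC	NPTRLLVS*VAFVNLDA	TRBV18*00(100)	TRBJ1-5*00(100)	FALSE
30	2	0.000999500249875062	CTTGAACTATGACTGACTTTCGAGTCGGAGTCA	LEL*LTFESES	TRBV7-2*00(100)	TRBJ1-5*00(100)	FALSE
31	2	0.000999500249875062	TTCCTAACTTCCGGGAATTTGCATAAGGTGCAG	FLTSGNLHKVQ	TRBV18*00(100)	TRBJ2-1*00(100)	FALSE
32	1	0.000499750124937531	ACACCCACGACCGGTCACGCCGTAGTAAACTCGACCAGTAGGCGATCGGCGAGACCTCGA	TPTTGHAVVNSTSRRSARPR	TRBV9*00(100)	TRBJ1-2*00(100)	FALSE
33	1	0.000499750124937531	AGCCAAGTTTCGAGCAATAGTGGCCACGGGCACCGGAAGTTCTAAGCTGTGGCTAAGTGA	SQVSSNSGHGHRKF*AVAK*	TRBV28*00(100)	TRBJ1-2*00(100)	FALSE
34	1	0.000499750124937531	CATGACTTCGGATGGGGCCCAGAAGCGGAA	HDFGWGPEAE	TRBV27*00(100)	TRBJ1-6*00(100)	FALSE
35	1	0.000499750124937531	CGCTTTGAGCCG			TRBJ2-5*00(100)	TRUE
36	1	0.000499750124937531	GAGCTTTAATGCCCATATACTTCGGGTGCTTCCCCGCGGGTCCTCCGCATAGGA	EL*CPYTSGASPRVLRIG	TRBV9*00(100)	TRBJ1-6*00(100)	FALSE
37	1	0.000499750124937531	GATTTGGCAAGTAACACTTGGGATTAAGAACCTCGTCGATCAAAGAAAATT	DLASNTWD*EPRRSKKI	TRBV27*00(100)	TRBJ2-7*00(100)	FALSE
38	1	0.000499750124937531	GGAGTCTCCTCAGCTTAGATTTCTTCTCTC	GVSSA*ISSL	TRBV25-1*00(100)	TRBJ2-7*00(100)	FALSE
39	1	0.000499750124937531	TATCCTCTTTCGGTATGTGCGCCGACTAGT	YPLSVCAPTS	TRBV15*00(100)	TRBJ1-5*00(100)	FALSE
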