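cloneId	readCount	readFraction	nSeqCDR3	aaSeqCDR3	allVHitsWithScore	allJHitsWithScore	isPartial
0	879	0.436444885799404	CAGGGGGCCCACTACAACTTGCGCCCTTCCTCTGCTTTCCCTCGGAGGGTC	QGAHYNLRPSSAFPRRV	TRBV7-9*00(100)	TRBJ1-2*00(100)	FALSE
1	407	0.202085402184707	CCGGCTAAGCCCCTCAATTTCTATCCT	PAKPLNFYP	TRBV13*00(100)	TRBJ2-2*00(100)	FALSE
2	395	0.196127110228401	GTAAATCAATGCCACCGACACATCCCGGAAACCTTC	VNQCHRHIPETF	TRBV5-1*00(100)	TRBJ1-2*00(100)	FALSE
3	138	0.0685203574975174	GTGATGATTGTCCTCAATCTGGGT	VMIVLNLG	TRBV24-1*00(100)	TRBJ2-7*00(100)	FALSE
4	47	0.0233366434955313	TATACCCCGACCGACGTTTTACGGGATCGGATAACAAAT	YTPTDVLRDRITN	TRBV7-9*00(100)	TRBJ1-6*00(100)	FALSE
5	32	0.015888778550149	ATAGCTGTACACCGGCCTCCCCAC	IAVHRPPH	TRBV28*00(100)	TRBJ2-5*00(100)	FALSE
6	17	0.00844091360476663	CTGATGACAGTCTAGGCTATTCCCGAGCTCAATTCGATT	LMTV*AIPELNSI	TRBV30*00(100)	TRBJ1-3*00(100)	FALSE
7	13	0.00645481628599801	TAGGGCGAGAGGGTTCCTCCTGGCTACGGAGTCTCTGGCTTCACACGTAACCGT	*GERVPPGYGVSGFTRNR	TRBV30*00(100)	TRBJ1-5*00(100)	FALSE
8	9	0.00446871896722939	GGGACAGGGTCCCTTGAAGAAGTG	GTGSLEEV	TRBV20-1*00(100)	TRBJ2-5*00(100)	FALSE
9	7	0.00347567030784508	GATTAGCAAACGGTGCGTAAACTC	D*QTVRKL	TRBV27*00(100)	TRBJ2-6*00(100)	FALSE
10	6	0.00297914597815293	AAGCGGACCTAG			TRBJ1-3*00(100)	TRUE
11	5	0.00248262164846077	GACTAGGTACAAGCTTTCCGATGGGGCTCGGTGTCGCCTATTTCGCCAAAG	D*VQAFRWGSVSPISPK	TRBV28*00(100)	TRBJ1-6*00(100)	FALSE
12	5	0.00248262164846077	GCCAGAAGATTTACGGGGCACTGTTTTTATTCGAGTATGATATCAAGCTTA	ARRFTGHCFYSSMISSL	TRBV5-1*00(100)	TRBJ2-2*00(100)	FALSE
13	4	0.00198609731876862	AAGATACCTCTGGACAGGTATCCGTTCTGATAC	KIPLDRYPF*Y	TRBV9*00(100)	TRBJ1-6*00(100)	FALSE
14	4	0.00198609731876862	ACGTTTACCCCGCTCCCTCCATAGTCGATTGAAGCGCGTCTAATGTATCATGGAGTA	TFTPLPP*SIEARLMYHGV	TRBV6-5*00(100)	TRBJ2-6*00(100)	FALSE
15	4	0.00198609731876862	CGGGCTGAGCTC			TRBJ2-2*00(100)	TRUE
16	4	0.00198609731876862	GAGACTTATTTGTGGTTAACCTCTTACGCCTTCCGGGTACGGGCTGAGCTC	ETYLWLTSYAFRVRAEL	TRBV25-1*00(100)	TRBJ2-2*00(100)	FALSE
17	4	0.00198609731876862	TAGTTATCTGAGCCCGCGTTACTGAACGTACGT	*LSEPALLNVR	TRBV28*00(100)	TRBJ2-6*00(100)	FALSE
18	4	0.00198609731876862	TATCTCCCAAATACAGTGTCGGCTACAGCCGAAGTT	YLPNTVSATAEV	TRBV6-5*00(100)	TRBJ2-5*00(100)	FALSE
19	4	0.00198609731876862	TGACTACAACCTCCATGATCGAGTTATGAGTAC	*LQPP*SSYEY	TRBV9*00(100)	TRBJ1-3*00(100)	FALSE
20	3	0.00148957298907646	CGGAGTACAGTCCAACCAGGGCCCTGG	RSTVQPGPW	TRBV6-1*00(100)	TRBJ2-6*00(100)	FALSE
21	3	0.00148957298907646	GGCTAAGACATGCTACACAGACGTGCCTTTCATGAGTCTTCC	G*DMLHRRAFHESS	TRBV4-1*00(100)	TRBJ1-2*00(100)	FALSE
22	3	0.00148957298907646	TACAGAACGAAGTAAGCAATGACACACAACTGATTG	YRTK*AMTHN*L	TRBV2*00(100)	TRBJ2-5*00(100)	FALSE
23	3	0.00148957298907646	TATCTCCCAAAT		TRBV6-5*00(100)		TRUE
24	2	0.00099304865938431	AAACAGGGTTTCGTGCTTTAATATCCCTCGCCTCCCCACTATCGTTACTCAGCA	KQGFVL*YPSPPHYRYSA	TRBV12-3*00(100)	TRBJ2-5*00(100)	FALSE
25	2	0.00099304865938431	ACTCACACGCAATTCCTACAGATGCACATAGTGAGTGAGATAAAGCGGACCTAG	THTQFLQMHIVSEIKRT*	TRBV15*00(100)	TRBJ1-3*00(100)	FALSE
26	1	0.000496524329692155	ACTTGAGCGCATGCCACCGACGCCGCACAGTATAGATGGCGC	T*AHATDAAQYRWR	TRBV29-1*00(100)	TRBJ1-3*00(100)	FALSE
27	1	0.000496524329692155	AGGCATTTTAATACCCGCACTTCCCTCTGCCATGGGGGTCGCCCG	RHFNTRTSLCHGGRP	TRBV7-9*00(100)	TRBJ1-5*00(100)	FALSE
28	1	0.000496524329692155	ATATGTTCATTTAGGTCTTGAACGGAGTCAAAGCTGACT	ICSFRS*TESKLT	TRBV2*00(100)	TRBJ1-5*00(100)	FALSE
29	1	0.000496524329692155	CCTCCACTACGGTATTACGTACCA	PPLRYYVP	TRBV9*00(100)	TRBJ1-6*00(100)	FALSE
30	1	0.000496524329692155	CTCCGTGTTTTAACGTCCCGCTATACGTGCGAC	LRVLTSRYTCD	TRBV30*00(100)	TRBJ2-2*00(100)	FALSE
31	1	0.000496524329692155	GTACTGCGCCTTCTCATGTCCTGTAAACCTGGCCAATAGTTAGCAGGGGGA	VLRLLMSCKPGQ*LAGG	TRBV28*00(100)	TRBJ1-2*00(100)	FALSE
32	1	0.000496524329692155	TAGCTTAGACTGCCTGAGCCTCCACGAGTTTTGGGTCTGGGTTTGACGGTAGCCTATTTG	*LRLPEPPRVLGLGLTVAYL	TRBV29-1*00(100)	TRBJ2-6*00(100)	FALSE
33	1	0.000496524329692155	TATAGATGGCGC			TRBJ1-3*00(100)	TRUE
34	1	0.000496524329692155	TCGACAGCACAGTATATTATTGGATCG	STAQYIIGS	TRBV6-5*00(100)	TRBJ2-3*00(100)	FALSE
35	1	0.000496524329692155	TGCGCCTCACTGCAGTTCCACCGATAATTGGGGTACATC	CASLQFHR*LGYI	TRBV5-1*00(100)	TRBJ2-5*00(100)	FALSE
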