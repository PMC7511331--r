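cloneId	readCount	readFraction	nSeqCDR3	aaSeqCDR3	allVHitsWithScore	allJHitsWithScore	isPartial
0	669	0.333999001497753	CTCGTATCACTTACTGTGTCTGTAAACAGAGCGACTTCCGTCCAATGTTGTGGA	LVSLTVSVNRATSVQCCG	TRBV9*00(100)	TRBJ2-1*00(100)	FALSE
1	271	0.135297054418372	ATTCCGGAAGACTAGCAAGATAAGGAT	IPED*QDKD	TRBV28*00(100)	TRBJ2-4*00(100)	FALSE
2	153	0.0763854218671992	TATTTGAACTCCCCATATTAAGGGCGTTCCCATGGA	YLNSPY*GRSHG	TRBV5-1*00(100)	TRBJ1-2*00(100)	FALSE
3	93	0.0464303544682976	TTACTTTACACATTTGAGTGACGTCACCGTCGA	LLYTFE*RHRR	TRBV9*00(100)	TRBJ2-7*00(100)	FALSE
4	67	0.0334498252621068	AGCTTCAGATAGGAGCAGATCCTGAAA	SFR*EQILK	TRBV4-1*00(100)	TRBJ1-2*00(100)	FALSE
5	48	0.0239640539191213	ATAAGGTCTTTATGCGGCGTAAAG	IRSLCGVK	TRBV9*00(100)	TRBJ1-3*00(100)	FALSE
6	45	0.0224663005491762	ACCTCCTTCGCCTATATTGTTTGCGAC	TSFAYIVCD	TRBV9*00(100)	TRBJ1-5*00(100)	FALSE
7	43	0.0214677983025462	GCTGGTCGCGGCACAGGGTTTAGTAGACTCAGGATA	AGRGTGFSRLRI	TRBV5-1*00(100)	TRBJ2-6*00(100)	FALSE
8	42	0.0209685471792312	ATGTTAGAGGAAGACAAGAGACCGGGGAGTGTATTCCGCGAAGCTGAGCCCCGTAGG	MLEEDKRPGSVFREAEPRR	TRBV7-2*00(100)	TRBJ1-3*00(100)	FALSE
9	41	0.0204692960559161	GGTCACAGAGGTACACTTAAATCGAGGCGC	GHRGTLKSRR	TRBV13*00(100)	TRBJ1-1*00(100)	FALSE
10	39	0.0194707938092861	CCGGCTAAGCCCCTCAATTTCTATCCT	PAKPLNFYP	TRBV13*00(100)	TRBJ2-2*00(100)	FALSE
11	38	0.018971542685971	AGCTGCTTCATGGCAACGGTACCTGGCCCTCGCCCCTTCATACCACTCGGA	SCFMATVPGPRPFIPLG	TRBV7-2*00(100)	TRBJ2-4*00(100)	FALSE
12	37	0.018472291562656	CAGGGGGCCCACTACAACTTGCGCCCTTCCTCTGCTTTCCCTCGGAGGGTC	QGAHYNLRPSSAFPRRV	TRBV7-9*00(100)	TRBJ1-2*00(100)	FALSE
13	37	0.018472291562656	CTCGTACCAGAGGCGAGTCGTTGACGGTAAATGTGC	LVPEASR*R*MC	TRBV11-2*00(100)	TRBJ2-2*00(100)	FALSE
14	36	0.017973040439341	CGGGGCTTGCTAGTAAGTCAACCA	RGLLVSQP	TRBV25-1*00(100)	TRBJ1-6*00(100)	FALSE
15	27	0.0134797803295057	CCATATCTACAACCAATGTAACTCCCCTCCTCAAGC	PYLQPM*LPSSS	TRBV12-3*00(100)	TRBJ1-3*00(100)	FALSE
16	27	0.0134797803295057	TCTCTATGCGATCCTAATCCTGCA	SLCDPNPA	TRBV6-5*00(100)	TRBJ1-5*00(100)	FALSE
17	26	0.0129805292061907	GAATTCACGAGCTAATCCTCATTAATAAATCGGACCCCCTAATGCTTA	EFTS*SSLINRTP*CL	TRBV18*00(100)	TRBJ1-4*00(100)	FALSE
18	24	0.0119820269595607	CTCATTCAGGCGGTACATTACTCTTCTTGTTAATTGAGCGGTGAGTCGCTCACCGACCTA	LIQAVHYSSC*LSGESLTDL	TRBV5-1*00(100)	TRBJ2-3*00(100)	FALSE
19	19	0.00948577134298552	AAAATAGCCCATACTGCGGCCGACCCTCTGTTCAGAATCCCTTTT	KIAHTAADPLFRIPF	TRBV6-5*00(100)	TRBJ2-1*00(100)	FALSE
20	18	0.00898652021967049	GATCTACGTATCCCTGCCTGCGGAGGGTGATACGGGGCGTTTCAACCAGTTCAGCCCGTG	DLRIPACGG*YGAFQPVQPV	TRBV15*00(100)	TRBJ2-1*00(100)	FALSE
21	18	0.00898652021967049	GCGTGCGCTTTGCAGAGACGCCCCTCAATAGGAACTTGAACACGAATCTAAGCTTTC	ACALQRRPSIGT*TRI*AF	TRBV11-2*00(100)	TRBJ1-4*00(100)	FALSE
22	18	0.00898652021967049	TGACCAAAAGGCGCGTCGCGCCTCTACTAAGTTAGATGGGAAGTGGTCACGCGGGTG	*PKGASRLY*VRWEVVTRV	TRBV27*00(100)	TRBJ2-2*00(100)	FALSE
23	13	0.00649026460309536	TACCGGGCCTTTCGGACAGATAATGTCCCCAGCTTTAGGCCA	YRAFRTDNVPSFRP	TRBV18*00(100)	TRBJ2-4*00(100)	FALSE
24	13	0.00649026460309536	TGGGCTCAGAGCTATGCGAGACATTTGAGTGAC	WAQSYARHLSD	TRBV13*00(100)	TRBJ2-5*00(100)	FALSE
25	12	0.00599101347978033	GTAAATCAATGCCACCGACACATCCCGGAAACCTTC	VNQCHRHIPETF	TRBV5-1*00(100)	TRBJ1-2*00(100)	FALSE
26	11	0.0054917623564653	GGTAGTATAATCTGTAAGTAGTTGGATGTTGGT	GSIICK*LDVG	TRBV4-1*00(100)	TRBJ1-4*00(100)	FALSE
27	11	0.0054917623564653	TGCATTAATGACAGGCAGCATGTAGGTGCGGAGAACCGCAAGTCAATCCACATT	CINDRQHVGAENRKSIHI	TRBV24-1*00(100)	TRBJ2-3*00(100)	FALSE
28	9	0.00449326010983525	TAGGAATAGACGTTCTCCCATTTGGATCGGCGTGTAACGACTCGGTTCAAACAG	*E*TFSHLDRRVTTRFKQ	TRBV29-1*00(100)	TRBJ2-4*00(100)	FALSE
29	8	0.00399400898652022	AAATGGGAGTAAGGATGCGGATTAGTATGCGGAATTAGG	KWE*GCGLVCGIR	TRBV15*00(100)	TRBJ2-3*00(100)	FALSE
30	7	0.00349475786320519	AGCATCCAGAAGGTGAGTTCACGAATTTTTGACTAGCCTCCGGCCGTTCACCGA	SIQKVSSRIFD*PPAVHR	TRBV27*00(100)	TRBJ2-6*00(100)	FALSE
31	7	0.00349475786320519	CCATCATTTGTTATAGGATGCGTAGCCCCCCTGTCGACAACGTGAATCATTCAC	PSFVIGCVAPLSTT*IIH	TRBV9*00(100)	TRBJ2-4*00(100)	FALSE
32	6	0.00299550673989016	GACTGACTACAGGGGAGGGAGTCCGAAGGAACGAGAGATAGATTTCGACGC	D*LQGRESEGTRDRFRR	TRBV6-1*00(100)	TRBJ1-5*00(100)	FALSE
33	6	0.00299550673989016	TACTCAACATATCGCTACTGCGATCCATTGTTGCCACGTAGCGCT	YSTYRYCDPLLPRSA	TRBV15*00(100)	TRBJ1-1*00(100)	FALSE
34	6	0.00299550673989016	TTAGTCGTCATCTGTCTTGAACCCAAAGGTAGGAGCGAGTTG	LVVICLEPKGRSEL	TRBV6-1*00(100)	TRBJ2-2*00(100)	FALSE
35	5	0.00249625561657514	ACACTTGGCCCTACGATAAACCGCGCCGCGGACGGCCGG	TLGPTINRAADGR	TRBV20-1*00(100)	TRBJ1-4*00(100)	FALSE
36	5	0.00249625561657514	AGCGCGAGGACCGAGCCCGGGCGATATACGGGTACA	SARTEPGRYTGT	TRBV20-1*00(100)	TRBJ1-2*00(100)	FALSE
37	5	0.00249625561657514	CTCTGGAACTCTGGGTACCGCTACAATGTTGGCATGGTGTCGCGAGGCGCGCTA	LWNSGYRYNVGMVSRGAL	TRBV30*00(100)	TRBJ1-2*00(100)	FALSE
38	5	0.00249625561657514	TACAACCGCCGAGTTGGTGTAACCTATACACTATGCCCGCTGAGA	YNRRVGVTYTLCPLR	TRBV27*00(100)	TRBJ2-6*00(100)	FALSE
39	4	0.00199700449326011	AAAGCGGGTATTGCTGCCTTGACTCAATAAAGTTTT	KAGIAALTQ*SF	TRBV27*00(100)	TRBJ2-4*00(100)	FALSE
40	4	0.00199700449326011	ATCGCTGCATGTGTCTAGTAGGGAACCAATGAACCGCCTAACTCC	IAACV**GTNEPPNS	TRBV5-1*00(100)	TRBJ1-3*00(100)	FALSE
41	4	0.00199700449326011	CCAGTTAATACGGGCCAAACCTATTAAGGTTTC	PVNTGQTY*GF	TRBV24-1*00(100)	TRBJ2-6*00(100)	FALSE
42	4	0.00199700449326011	CCTAGTTTCGTTTGGGCGCATAGCCATCTGTAA	PSFVWAHSHL*	TRBV6-1*00(100)	TRBJ1-3*00(100)	FALSE
43	3	0.00149775336994508	AGTTCATTCCTATCAGGCAACTCCGAG	SSFLSGNSE	TRBV9*00(100)	TRBJ1-3*00(100)	FALSE
44	3	0.00149775336994508	CCTTTTCCAAAACAGGCGGTACGATAGACTTGACCATGTGGG	PFPKQAVR*T*PCG	TRBV6-5*00(100)	TRBJ1-3*00(100)	FALSE
45	3	0.00149775336994508	CGTCACCGTCGA			TRBJ2-7*00(100)	TRUE
46	3	0.00149775336994508	GAAAACTCTGTGGATTTCTTATACTAATCCAAGCTGCTGCTACAT	ENSVDFLY*SKLLLH	TRBV15*00(100)	TRBJ1-5*00(100)	FALSE
47	3	0.00149775336994508	TAGCTGCCCCAGGAAACGGTACCCCAA	*LPQETVPQ	TRBV11-2*00(100)	TRBJ2-2*00(100)	FALSE
48	3	0.00149775336994508	TCGCTCCCCTTAAAGTGACCGTTCCGTACATACTTC	SLPLK*PFRTYF	TRBV2*00(100)	TRBJ2-5*00(100)	FALSE
49	2	0.000998502246630055	AGTACTTCGACTTAACGTAGCTGCGTTGTACGCTCAACCGTGAAC	STST*RSCVVRSTVN	TRBV6-1*00(100)	TRBJ2-3*00(100)	FALSE
50	2	0.000998502246630055	CGGATGGAAGTATTATGCGAAGGCCGGGAG	RMEVLCEGRE	TRBV9*00(100)	TRBJ2-5*00(100)	FALSE
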