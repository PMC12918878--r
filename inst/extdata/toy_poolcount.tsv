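barcode	rcbarcode	scaffold	strand	pos	gene	d0_a	d0_b	d0_c	d1_a	d1_b	d1_c	d4_a	d4_b	d4_c	d10_a	d10_b	d10_c
TCCACAAGCCGCAGATCACG	CGTGATCTGCGGCTTGTGGA	sc1	-	14118	b0001	397	454	335	384	343	361	372	353	414	401	422	376
TTCTTCTTAAGTAAAAGGTC	GACCTTTTACTTAAGAAGAA	sc1	+	18447	b0002	140	174	142	169	179	163	154	154	175	189	188	160
AAATATCGGAGACACGCCCT	AGGGCGTGTCTCCGATATTT	sc1	+	81279	b0005	65	61	73	52	40	48	41	56	56	5983	6350	6018
AATCAGCTCGCAAGATTGTT	AACAATCTTGCGAGCTGATT	sc2	-	1183	b0007	28	29	21	21	19	29	60	61	61	4	5	7
CCTACGACTTTCATATTCCC	GGGAATATGAAAGTCGTAGG	sc1	-	30852	b0003	139	128	93	98	100	108	130	114	113	124	129	121
ACAATTGGGGTCTCAGCAGT	ACTGCTGAGACCCCAATTGT	sc1	-	38995	b0004	552	533	499	529	510	559	277	240	282	3041	3195	3179
CAAACCCTGCTAGTCAGCCG	CGGCTGACTAGCAGGGTTTG	sc2	-	15424	b0008	299	330	279	376	358	354	284	260	312	221	225	239
GATACTACAGCCTTGCTTAT	ATAAGCAAGGCTGTAGTATC	sc1	-	10441	b0001	180	139	144	158	156	144	141	126	128	142	154	166
GATGCTGATACTCACTAAGC	GCTTAGTGAGTATCAGCATC	sc2	+	29039	b0009	546	553	504	541	439	487	41	47	43	30	26	23
GAATTCACGTCGCCGTATCG	CGATACGGCGACGTGAATTC	sc2	+	5297	b0007	131	143	142	125	101	136	392	320	399	20	25	23
CCCTTACGTTGGGTCCACGC	GCGTGGACCCAACGTAAGGG	sc1	+	29071	b0003	475	497	478	452	436	463	435	431	474	510	529	507
AGGGATCTCGGTGGACAAAT	ATTTGTCCACCGAGATCCCT	sc2	-	49938	b0010	36	37	35	54	50	45	12	21	16	24	21	22
TAGGTGGCGAGACGAACCCA	TGGGTTCGTCTCGCCACCTA	sc2	-	58150	b0010	181	189	182	284	250	270	86	75	102	100	96	101
TTATTCGGAGTGTCTTTGGT	ACCAAAGACACTCCGAATAA	sc1	+	81496	b0006	141	144	153	118	107	100	218	207	244	240	222	243
ATGGGGCCATTAAGCTCGCT	AGCGAGCTTAATGGCCCCAT	sc2	+	2511	b0007	158	137	148	139	112	146	418	336	407	41	40	23
TATGCCACCATTCAGTATCG	CGATACTGAATGGTGGCATA	sc1	-	87947	b0006	169	222	218	179	150	165	311	323	319	314	384	339
GGCAAACGTTGTAAGTATGT	ACATACTTACAACGTTTGCC	sc1	-	25749	b0002	733	764	712	797	707	754	786	751	785	759	825	782
CATCCAAAAATGAGCATATC	GATATGCTCATTTTTGGATG	sc1	+	14835	b0002	210	229	161	218	186	221	228	191	201	225	233	216
GTCGTTGAGCCGCTTATTCC	GGAATAAGCGGCTCAACGAC	sc2	+	8201	b0008	141	154	138	177	167	199	169	144	165	112	116	123
GGATTAATAACCGTACGTTG	CAACGTACGGTTATTAATCC	sc1	+	1825	b0001	398	376	376	371	325	350	373	296	367	381	401	420
AAGCTTACATCCGGTAGTAC	GTACTACCGGATGTAAGCTT	sc2	-	41332	b0009	388	425	362	386	335	384	31	28	35	23	29	29
GTTTAAAGAACGTGATGAGT	ACTCATCACGTTCTTTAAAC	sc1	+	86056	b0006	140	112	104	96	77	96	204	147	180	156	165	170
CTGGGTCCCGAGCGAGTGTG	CACACTCGCTCGGGACCCAG	sc1	+	71992	b0005	148	168	145	92	100	104	133	100	133	13908	14344	13765
CTGCCTATAATGCTGGCGCA	TGCGCCAGCATTATAGGCAG	sc2	+	43131	b0010	423	443	434	626	540	596	214	210	197	212	217	212
AAGCCTGTCTAGGCGAATAA	TTATTCGCCTAGACAGGCTT	sc1	+	57408	b0004	86	90	64	86	90	82	31	42	32	487	494	486
GTAATGCGTTATGGCTCCCT	AGGGAGCCATAACGCATTAC	sc1	-	79360	b0005	35	34	42	33	24	25	32	38	30	3781	3935	3862
GGTTGGCCGCCCAGTAAAAT	ATTTTACTGGGCGGCCAACC	sc2	+	8665	b0008	162	171	162	234	226	238	160	150	182	118	134	123
TTAGTGGGTACTTTCTGGCT	AGCCAGAAAGTACCCACTAA	sc1	+	27451	b0003	168	169	163	168	154	157	144	159	175	181	203	171
CACAAACGCTGCGCGTTTCC	GGAAACGCGCAGCGTTTGTG	sc2	-	42138	b0009	45	53	54	51	37	34	7	4	1	5	0	2
GCAGGTCCCTGCGGCCTTCT	AGAAGGCCGCAGGGACCTGC	sc1	-	35232	b0004	247	298	268	276	236	293	139	125	151	1619	1656	1667
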