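name	start	end	strand	category	letter_code	size_printed	spacer_printed	aa_printed	start_codon	stop_codon
tRNA-Phe	1	68	H	tRNA	F	68	0	NA	NA	NA
12S-rRNA	69	1015	H	rRNA	NA	947	0	NA	NA	NA
tRNA-Val	1016	1087	H	tRNA	V	72	0	NA	NA	NA
16S-rRNA	1088	2779	H	rRNA	NA	1692	0	NA	NA	NA
tRNA-Leu(UUR)	2780	2853	H	tRNA	L1	74	0	NA	NA	NA
ND1	2854	3828	H	PCG	NA	975	3	324	ATG	TAG
tRNA-Ile	3832	3903	H	tRNA	I	72	-2	NA	NA	NA
tRNA-Gln	3902	3972	L	tRNA	Q	71	-1	NA	NA	NA
tRNA-Met	3972	4042	H	tRNA	M	71	0	NA	NA	NA
ND2	4043	5088	H	PCG	NA	1046	0	348	ATG	TA
tRNA-Trp	5089	5159	H	tRNA	W	71	1	NA	NA	NA
tRNA-Ala	5161	5229	L	tRNA	A	69	1	NA	NA	NA
tRNA-Asn	5231	5303	L	tRNA	N	73	1	NA	NA	NA
OL	5305	5341	H	origin	NA	37	-3	NA	NA	NA
tRNA-Cys	5339	5405	L	tRNA	C	67	2	NA	NA	NA
tRNA-Tyr	5408	5478	L	tRNA	Y	69	1	NA	NA	NA
COI	5480	7030	H	PCG	NA	1551	0	516	GTG	TAA
tRNA-Ser(UCN)	7031	7101	L	tRNA	S1	71	3	NA	NA	NA
tRNA-Asp	7105	7177	H	tRNA	D	73	6	NA	NA	NA
COII	7184	7874	H	PCG	NA	691	0	230	ATG	T
tRNA-Lys	7875	7948	H	tRNA	K	74	1	NA	NA	NA
ATP8	7950	8117	H	PCG	NA	168	-10	55	ATG	TAA
ATP6	8108	8790	H	PCG	NA	683	0	227	ATG	TA
COIII	8791	9575	H	PCG	NA	785	0	261	ATG	TA
tRNA-Gly	9576	9647	H	tRNA	G	72	0	NA	NA	NA
ND3	9648	9996	H	PCG	NA	349	0	116	ATG	T
tRNA-Arg	9997	10065	H	tRNA	R	69	0	NA	NA	NA
ND4L	10066	10362	H	PCG	NA	297	-7	98	ATG	TAA
ND4	10356	11736	H	PCG	NA	1381	0	460	ATG	T
tRNA-His	11737	11805	H	tRNA	H	69	0	NA	NA	NA
tRNA-Ser(AGY)	11806	11873	H	tRNA	S2	68	4	NA	NA	NA
tRNA-Leu(CUN)	11878	11950	H	tRNA	L2	73	0	NA	NA	NA
ND5	11951	13789	H	PCG	NA	1839	-4	612	ATG	TAA
ND6	13786	14307	L	PCG	NA	522	0	173	ATG	TAG
tRNA-Glu	14308	14376	L	tRNA	E	69	6	NA	NA	NA
CYTB	14383	15523	H	PCG	NA	1141	0	380	ATG	T
tRNA-Thr	15524	15595	H	tRNA	T	72	-1	NA	NA	NA
tRNA-Pro	15595	15664	L	tRNA	P	70	0	NA	NA	NA
D-loop	15665	16910	H	control	NA	1246	NA	NA	NA	NA
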