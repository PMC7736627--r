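name	start	end	strand	category	letter_code	size_printed	spacer_printed	aa_printed	start_codon	stop_codon
tRNA-Phe	1	68	H	tRNA	F	68	0	NA	NA	NA
12S-rRNA	69	1014	H	rRNA	NA	946	0	NA	NA	NA
tRNA-Val	1015	1086	H	tRNA	V	72	0	NA	NA	NA
16S-rRNA	1087	2778	H	rRNA	NA	1692	0	NA	NA	NA
tRNA-Leu(UUR)	2779	2852	H	tRNA	L1	74	0	NA	NA	NA
ND1	2853	3827	H	PCG	NA	975	5	324	ATG	TAA
tRNA-Ile	3833	3902	H	tRNA	I	70	-1	NA	NA	NA
tRNA-Gln	3902	3972	L	tRNA	Q	71	-1	NA	NA	NA
tRNA-Met	3972	4042	H	tRNA	M	71	0	NA	NA	NA
ND2	4043	5088	H	PCG	NA	1046	0	348	ATG	TA
tRNA-Trp	5089	5160	H	tRNA	W	71	1	NA	NA	NA
tRNA-Ala	5162	5230	L	tRNA	A	69	1	NA	NA	NA
tRNA-Asn	5232	5304	L	tRNA	N	73	1	NA	NA	NA
OL	5306	5342	H	origin	NA	37	-3	NA	NA	NA
tRNA-Cys	5340	5406	L	tRNA	C	65	2	NA	NA	NA
tRNA-Tyr	5409	5479	L	tRNA	Y	71	1	NA	NA	NA
COI	5481	7031	H	PCG	NA	1551	0	516	GTG	TAA
tRNA-Ser(UCN)	7032	7102	L	tRNA	S1	69	3	NA	NA	NA
tRNA-Asp	7106	7178	H	tRNA	D	73	6	NA	NA	NA
COII	7185	7875	H	PCG	NA	691	0	230	ATG	T
tRNA-Lys	7876	7949	H	tRNA	K	74	1	NA	NA	NA
ATP8	7951	8118	H	PCG	NA	168	-10	55	ATG	TAA
ATP6	8109	8791	H	PCG	NA	683	0	227	ATG	TA
COIII	8792	9576	H	PCG	NA	785	0	261	ATG	TA
tRNA-Gly	9577	9648	H	tRNA	G	72	0	NA	NA	NA
ND3	9649	9997	H	PCG	NA	349	0	116	ATG	T
tRNA-Arg	9998	10066	H	tRNA	R	69	0	NA	NA	NA
ND4L	10067	10363	H	PCG	NA	297	-7	98	ATG	TAA
ND4	10357	11737	H	PCG	NA	1381	0	460	ATG	T
tRNA-His	11738	11806	H	tRNA	H	69	0	NA	NA	NA
tRNA-Ser(AGY)	11807	11874	H	tRNA	S2	72	4	NA	NA	NA
tRNA-Leu(CUN)	11879	11951	H	tRNA	L2	73	0	NA	NA	NA
ND5	11952	13790	H	PCG	NA	1839	-4	612	ATG	TAA
ND6	13787	14308	L	PCG	NA	522	0	173	ATG	TAG
tRNA-Glu	14309	14377	L	tRNA	E	69	6	NA	NA	NA
CYTB	14384	15524	H	PCG	NA	1141	0	380	ATG	T
tRNA-Thr	15525	15596	H	tRNA	T	73	-1	NA	NA	NA
tRNA-Pro	15596	15665	L	tRNA	P	70	0	NA	NA	NA
D-loop	15666	17056	H	control	NA	1391	NA	NA	NA	NA
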