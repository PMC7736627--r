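name	start	end	strand	category	letter_code	size_printed	spacer_printed	aa_printed	start_codon	stop_codon
tRNA-Phe	1	68	H	tRNA	F	68	0	NA	NA	NA
12S-rRNA	69	1014	H	rRNA	NA	946	0	NA	NA	NA
tRNA-Val	1015	1086	H	tRNA	V	72	0	NA	NA	NA
16S-rRNA	1087	2778	H	rRNA	NA	1692	0	NA	NA	NA
tRNA-Leu(UUR)	2779	2852	H	tRNA	L1	74	0	NA	NA	NA
ND1	2853	3827	H	PCG	NA	975	3	324	ATG	TAA
tRNA-Ile	3831	3902	H	tRNA	I	72	-2	NA	NA	NA
tRNA-Gln	3901	3972	L	tRNA	Q	72	-2	NA	NA	NA
tRNA-Met	3971	4041	H	tRNA	M	71	0	NA	NA	NA
ND2	4042	5087	H	PCG	NA	1046	0	348	ATG	TA
tRNA-Trp	5088	5158	H	tRNA	W	71	1	NA	NA	NA
tRNA-Ala	5160	5228	L	tRNA	A	69	1	NA	NA	NA
tRNA-Asn	5230	5302	L	tRNA	N	73	0	NA	NA	NA
OL	5303	5340	H	origin	NA	38	-4	NA	NA	NA
tRNA-Cys	5337	5403	L	tRNA	C	67	2	NA	NA	NA
tRNA-Tyr	5406	5476	L	tRNA	Y	71	1	NA	NA	NA
COI	5478	7028	H	PCG	NA	1551	0	516	GTG	TAA
tRNA-Ser(UCN)	7029	7099	L	tRNA	S1	71	3	NA	NA	NA
tRNA-Asp	7103	7175	H	tRNA	D	73	6	NA	NA	NA
COII	7182	7872	H	PCG	NA	691	0	230	ATG	T
tRNA-Lys	7873	7946	H	tRNA	K	74	1	NA	NA	NA
ATP8	7948	8115	H	PCG	NA	168	-10	55	ATG	TAA
ATP6	8106	8788	H	PCG	NA	683	0	227	ATG	TA
COIII	8789	9573	H	PCG	NA	785	0	261	ATG	TA
tRNA-Gly	9574	9645	H	tRNA	G	72	0	NA	NA	NA
ND3	9646	9994	H	PCG	NA	349	0	116	ATG	T
tRNA-Arg	9995	10063	H	tRNA	R	69	0	NA	NA	NA
ND4L	10064	10360	H	PCG	NA	297	-7	98	ATG	TAA
ND4	10354	11734	H	PCG	NA	1381	0	460	ATG	T
tRNA-His	11735	11803	H	tRNA	H	69	0	NA	NA	NA
tRNA-Ser(AGY)	11804	11871	H	tRNA	S2	68	4	NA	NA	NA
tRNA-Leu(CUN)	11876	11948	H	tRNA	L2	73	0	NA	NA	NA
ND5	11949	13787	H	PCG	NA	1839	-4	612	ATG	TAA
ND6	13784	14305	L	PCG	NA	522	0	173	ATG	TAG
tRNA-Glu	14306	14374	L	tRNA	E	69	6	NA	NA	NA
CYTB	14381	15521	H	PCG	NA	1141	0	380	ATG	T
tRNA-Thr	15522	15593	H	tRNA	T	72	-1	NA	NA	NA
tRNA-Pro	15593	15662	L	tRNA	P	70	0	NA	NA	NA
D-loop	15663	17580	H	control	NA	1918	NA	NA	NA	NA
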