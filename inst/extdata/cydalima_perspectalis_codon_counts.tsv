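Codon	AminoAcid	Count	RSCUPublished
UUU	F	350	1.87
UUC	F	24	0.13
UUA	L	467	5.28
UUG	L	17	0.19
CUU	L	23	0.26
CUC	L	2	0.02
CUA	L	22	0.25
CUG	L	0	0
AUU	I	442	1.88
AUC	I	27	0.12
AUA	M	258	1.81
AUG	M	27	0.19
GUU	V	76	2.14
GUC	V	4	0.11
GUA	V	62	1.75
GUG	V	0	0
UCU	S	109	2.73
UCC	S	9	0.23
UCA	S	85	2.13
UCG	S	1	0.03
CCU	P	69	2.17
CCC	P	11	0.35
CCA	P	47	1.48
CCG	P	0	0
ACU	T	80	2.15
ACC	T	5	0.13
ACA	T	64	1.72
ACG	T	0	0
GCU	A	78	2.48
GCC	A	9	0.29
GCA	A	37	1.17
GCG	A	2	0.06
UAU	Y	185	1.92
UAC	Y	8	0.08
UAA	*	11	2
UAG	*	0	0
CAU	H	65	1.88
CAC	H	4	0.12
CAA	Q	60	1.94
CAG	Q	2	0.06
AAU	N	231	1.87
AAC	N	16	0.13
AAA	K	97	1.8
AAG	K	11	0.2
GAU	D	62	1.94
GAC	D	2	0.06
GAA	E	72	1.89
GAG	E	4	0.11
UGU	C	28	1.87
UGC	C	2	0.13
UGA	W	91	1.94
UGG	W	3	0.06
CGU	R	20	1.51
CGC	R	0	0
CGA	R	31	2.34
CGG	R	2	0.15
AGU	S	17	0.43
AGC	S	0	0
AGA	S	98	2.46
AGG	S	0	0
GGU	G	73	1.42
GGC	G	2	0.04
GGA	G	114	2.22
GGG	G	16	0.31
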