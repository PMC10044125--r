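Gene	Strand	Location	Size	Intergenic	Anticodon	StartCodon	StopCodon
trnM	F	1–68	68	0	CAT	–	–
trnI	F	69–134	66	−3	GAT	–	–
trnQ	R	132–200	69	43	TTG	–	–
nad2	F	244–1,257	1014	1	–	ATT	TAA
trnW	F	1,259–1,325	67	−8	TCA	–	–
trnC	R	1,318–1,383	66	3	GCA	–	–
trnY	R	1,387–1,451	65	9	GTA	–	–
cox1	F	1,461–2,996	1536	−5	–	CGA	TAA
trnL2	F	2,992–3,058	67	0	TAA	–	–
cox2	F	3,059–3,740	682	0	–	ATG	T
trnK	F	3,741–3,811	71	13	CTT	–	–
trnD	F	3,825–3,890	66	0	GTC	–	–
atp8	F	3,891–4,052	162	−7	–	ATC	TAA
atp6	F	4,046–4,720	675	−1	–	ATG	TAA
cox3	F	4,720–5,508	789	2	–	ATG	TAA
trnG	F	5,511–5,576	66	0	TCC	–	–
nad3	F	5,577–5,930	354	16	–	ATT	TAA
trnA	F	5,947–6,011	65	0	TGC	–	–
trnR	F	6,012–6,074	63	1	TCG	–	–
trnN	F	6,076–6,141	66	6	GUU	–	–
trnS1	F	6,148–6,213	66	0	GCT	–	–
trnE	F	6,214–6,280	67	2	TTC	–	–
trnF	R	6,283–6,349	67	12	GAA	–	–
nad5	R	6,362–8,098	1737	0	–	ATA	T
trnH	R	8,099–8,164	66	1	GTG	–	–
nad4	R	8,166–9,506	1341	1	–	ATC	T
nad4L	R	9,508–9,798	291	2	–	ATA	T
trnT	F	9,801–9,867	67	0	TGT	–	–
trnP	R	9,868–9,933	66	2	TGG	–	–
nad6	F	9,936–10,472	537	6	–	ATT	TAA
cob	F	10,479–11,630	1152	−2	–	ATG	TAA
trnS2	F	11,629–11,693	65	17	TGA	–	–
nad1	R	11,711–12,649	939	1	–	ATA	T
trnL1	R	12,651–12,724	74	−44	TAG	–	–
16S	R	12,681–14,050	1370	4	–	–	–
trnV	R	14,055–14,124	70	−1	TAC	–	–
12S	R	14,124–14,892	769	0	–	–	–
A + T-rich		14,893–15,180	288	0	–	–	–
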