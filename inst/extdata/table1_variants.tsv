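patient_id	cohort	gene	transcript	exon	cdna_change	protein_change	zygosity	rsid	gnomad_af	revel	alphamissense	consequence	points_pre	points_post	printed_class_pre	printed_class_post
P2	1	PLCZ1	NM_033123.4	6	c.698A>T	p.His233Leu	het	rs200061726	0.0009183	0.256	0.171	missense	9	10	LP (P=0.988)	P (P=0.994)
P2	1	PLCZ1	NM_033123.4	9	c.964A>T	p.Lys322*	het	NA	0.00000159	NA	NA	nonsense	6	7	LP (P=0.9)	LP (P=0.949)
P3	1	PLCZ1	NM_033123.4	13	c.1499C>T	p.Ser500Leu	het	rs10505830	0.04151	0.099	0.086	missense	5	6	VUS (hot; P=0.812)	LP (P=0.9)
P4	1	PLCZ1	NM_033123.4	13	c.1499C>T	p.Ser500Leu	het	rs10505830	0.04151	0.099	0.086	missense	5	6	VUS (hot; P=0.812)	LP (P=0.9)
P7	1	PLCZ1	NM_033123.4	13	c.1499C>T	p.Ser500Leu	hom	rs10505830	0.04151	0.099	0.086	missense	5	6	VUS (hot; P=0.812)	LP (P=0.9)
P9	1	PLCZ1	NM_033123.4	5	c.422G>A	p.Arg141His	het	rs202034240	0.00002366	0.059	0.074	missense	3	4	VUS (tepid; P=0.5)	VUS (warm; P=0.675)
P15	1	PLCZ1	NM_033123.4	13	c.1499C>T	p.Ser500Leu	het	rs10505830	0.04151	0.099	0.086	missense	5	6	VUS (hot; P=0.812)	LP (P=0.9)
P18	1	PLCZ1	NM_033123.4	13	c.1499C>T	p.Ser500Leu	hom	rs10505830	0.04151	0.099	0.086	missense	5	6	VUS (hot; P=0.812)	LP (P=0.9)
P20	1	PLCZ1	NM_033123.4	13	c.1499C>T	p.Ser500Leu	hom	rs10505830	0.04151	0.099	0.086	missense	5	6	VUS (hot; P=0.812)	LP (P=0.9)
P21	1	PLCZ1	NM_033123.4	6	c.698A>T	p.His233Leu	het	rs200061726	0.0009183	0.256	0.171	missense	9	10	LP (P=0.988)	P (P=0.994)
P23	1	PLCZ1	NM_033123.4	13	c.1499C>T	p.Ser500Leu	hom	rs10505830	0.04151	0.099	0.086	missense	5	6	VUS (hot; P=0.812)	LP (P=0.9)
P26	1	PLCZ1	NM_033123.4	13	c.1499C>T	p.Ser500Leu	het	rs10505830	0.04151	0.099	0.086	missense	5	6	VUS (hot; P=0.812)	LP (P=0.9)
P26	1	PLCZ1	NM_033123.4	4	c.280C>T	p.Gln94*	het	rs138801851	0.0001370	NA	NA	nonsense	6	7	LP (P=0.9)	LP (P=0.949)
P29	2	ACTL7A	NM_006687.4	1	c.1088dup	p.Ser364Glnfs*9	hom	rs752334307	0.00006134	NA	NA	frameshift	7	11	LP (P=0.949)	P (P=0.997)
P32	2	PLCZ1	NM_033123.4	4	c.221T>C	p.Ile74Thr	het	rs145549980	0.0002654	0.045	0.068	missense	3	3	VUS (tepid; P=0.5)	VUS (tepid; P=0.5)
P32	2	ACTL7A	NM_006687.4	1	c.547T>C	p.Tyr183His	het	rs41278345	0.002240	0.704	0.880	missense	5	4	VUS (hot; P=0.812)	VUS (warm, P=0.675)
P34	2	PLCZ1	NM_033123.4	6	c.698A>T	p.His233Leu	het	rs200061726	0.0009183	0.256	0.171	missense	9	10	LP (P=0.988)	P (P=0.994)
P34	2	ACTL9	NM_178525.5	1	c.812G>C	p.Arg271Pro	het	rs73507819	0.02063	0.185	0.287	missense	1	1	VUS (cool; P=0.188)	VUS (cool; P=0.188)
P35	2	PLCZ1	NM_033123.4	6	c.698A>T	p.His233Leu	het	rs200061726	0.0009183	0.256	0.171	missense	9	10	LP (P=0.988)	P (P=0.994)
P36	2	PLCZ1	NM_033123.4	10	c.1136T>C	p.Ile379Thr	het	rs201548309	0.00005206	0.442	0.533	missense	5	6	VUS (hot; P=0.812)	LP (P=0.9)
P44	2	PLCZ1	NM_033123.4	6	c.698A>T	p.His233Leu	het	rs200061726	0.0009183	0.256	0.171	missense	9	10	LP (P=0.988)	P (P=0.994)
P46	2	ACTL7A	NM_006687.4	1	c.640G>A	p.Gly214Ser	hom	rs41278347	0.005301	0.891	0.798	missense	3	3	VUS (tepid; P=0.5)	VUS (tepid; P=0.5)
P46	2	ACTL7A	NM_006687.4	1	c.1117C>T	p.Arg373Cys	hom	rs775405375	0.00002540	0.910	0.947	missense	10	10	P (P=0.994)	P (P=0.994)
P54	2	ACTL7A	NM_006687.4	1	c.1018G>A	p.Val340Met	het	rs7872077	0.01517	0.197	0.113	missense	1	2	VUS (cold; P=0.188)	VUS (cool; P=0.325)
P54	2	ACTL7A	NM_006687.4	1	c.657G>A	p.Val219=	het	rs3739693	0.01408	NA	NA	synonymous	0	1	VUS (ice cold; P=0.1)	VUS (cold; P=0.188)
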