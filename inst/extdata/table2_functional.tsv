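patient_id	cohort	moat_two_cell	moat_mii	moat_group_printed	moca_n	moca_mean_axf	hoca_n	hoca_mean_axf
P2	1	5	26	1	17	2.15	10	0.00
P3	1	8	20	2	NA	NA	NA	NA
P4	1	21	27	2	NA	NA	NA	NA
P7	1	26	31	2	15	2.03	7	0.00
P9	1	20	24	2	16	10.35	8	0.10
P15	1	7	14	2	NA	NA	NA	NA
P18	1	13	24	2	11	39.17	14	0.60
P20	1	14	22	2	11	12.40	10	0.00
P21	1	17	19	3	10	13.00	13	0.00
P23	1	22	28	2	11	18.93	9	0.00
P26	1	26	29	3	7	33.24	8	0.00
P29	2	8	31	1-2	18	0.15	10	0.00
P32	2	26	28	3	14	94.63	11	3.24
P34	2	28	32	3	16	15.53	13	0.00
P35	2	19	24	2	16	22.02	9	0.00
P36	2	30	30	3	10	18.17	10	0.00
P44	2	20	25	2	NA	NA	NA	NA
P46	2	8	31	1-2	17	0.53	10	0.00
P54	2	3	42	1	14	1.08	11	0.00
C	NA	464	496	NA	42	85.71	58	3.88
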