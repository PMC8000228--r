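locus	motif	repeat_count	size_min	size_max	N	missing_pct	shannon	Ho	He
VF20_01	AT	6	203	205	2	0.00	0.66	0.00	0.48
VF20_02	AC	13	280	300	6	0.00	1.61	0.16	0.80
VF20_03	GA	6	177	197	7	0.00	1.24	0.26	0.62
VF20_05	AT	7	290	315	6	0.00	1.43	0.00	0.72
VF20_14	TC	7	218	245	6	5.26	1.51	0.11	0.75
VF20_17	AT	12	366	385	8	5.26	1.62	0.83	0.74
VF20_20	TA	9	116	130	5	0.00	1.47	0.42	0.76
VF20_21	TAT	7	176	196	6	0.00	1.33	0.37	0.67
VF20_22	GTA	6	117	119	2	0.00	0.58	0.00	0.40
VF20_24	TAT	6	358	392	6	15.79	1.20	0.12	0.59
VF20_37	AAAT	4	390	395	2	5.26	0.69	0.11	0.51
VF20_41	TCCC	4	391	394	2	21.05	0.69	0.00	0.51
VF20_43	TTTA	5	284	314	3	5.26	0.85	0.11	0.55
VF20_44	TCTT	4	363	376	4	0.00	1.37	0.84	0.76
VF20_46	TTTA	4	150	182	2	0.00	0.21	0.11	0.10
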