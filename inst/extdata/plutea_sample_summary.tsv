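sample_id	site	group	n_ccs_reads	n_processed_reads	n_otus	chao1	simpson	shannon	goods_coverage
MN1	MN	gulf	44117	30890	1282	1442.30	0.91	5.87	0.99
MN2	MN	gulf	26018	20453	958	1135.77	0.92	5.34	0.98
MN3	MN	gulf	24280	22707	517	702.11	0.83	4.49	0.99
TA1	TA	gulf	46466	44796	615	776.29	0.95	5.56	1.00
TA2	TA	gulf	24445	22974	523	637.18	0.96	5.98	0.99
TA3	TA	gulf	38438	35603	569	850.35	0.95	5.46	0.99
TL1	TL	gulf	25792	25562	331	464.17	0.93	5.14	1.00
TL2	TL	gulf	23307	23120	365	514.53	0.93	5.04	0.99
TL3	TL	gulf	25497	24709	367	468.27	0.90	4.91	1.00
MT1	MT	andaman	44083	43913	302	482.00	0.77	3.30	1.00
MT2	MT	andaman	41612	41384	285	426.22	0.68	2.39	1.00
MT3	MT	andaman	60478	60143	456	690.37	0.76	3.27	1.00
SM1	SM	andaman	45338	44254	410	616.90	0.78	2.87	1.00
SM2	SM	andaman	27841	26307	477	621.07	0.87	4.15	0.99
SM3	SM	andaman	33789	32179	282	453.27	0.75	2.48	1.00
TC1	TC	andaman	25103	24331	471	624.01	0.88	4.59	0.99
TC2	TC	andaman	24009	23374	288	509.69	0.83	3.34	0.99
TC3	TC	andaman	26182	25011	401	529.18	0.76	3.47	0.99
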