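patient	scorer	n_tot	n_ie	n_at	n_dt	ai_printed	n_bck	n_x	f_breath
1	S	324	5	7	3	4.6	237	36	13
2	S	375	16	6	4	6.9	105	1	15
3	S	565	41	0	5	8.2	39	14	22
4	S	459	18	15	3	8.1	65	30	15
5	S	498	69	147	6	44.6	0	72	32
6	S	430	4	63	3	16.3	254	12	17
7	S	743	29	221	3	34.1	0	9	36
8	S	497	33	183	13	46.1	251	17	24
9	S	310	3	0	0	1.6	2	0	12
1	E	307	9.4	14.1	1.6	8.4	186	NA	NA
2	E	360	22.0	3.5	2.7	7.8	84.7	NA	NA
3	E	541	46.5	5.2	4.0	10.0	37.7	NA	NA
4	E	449	16.8	18.2	3.6	8.7	53.2	NA	NA
5	E	498	71.8	44.5	1.3	23.1	1.8	NA	NA
6	E	430	1.6	64.4	1.6	16.5	253	NA	NA
7	E	743	12.8	24.8	1.3	7.3	1.8	NA	NA
8	E	492	24.6	88.4	1.6	31.8	24.4	NA	NA
9	E	312	1.6	1.8	1.6	1.7	9.4	NA	NA
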