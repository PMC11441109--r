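id	group	total_count	sequence	length	log2fc_interaction	sig_interaction	log2fc_dcl1	sig_dcl1	log2fc_dcl2	sig_dcl2
cro-mir-1	fungus	68544	UAGAAUUCGGGGUAGAAU	18	-1.83	TRUE	-0.07	FALSE	-5.84	TRUE
cro-mir-2	fungus	2032	UAGAAUUCGGGGUAGAAUG	19	-2.73	TRUE	0.49	FALSE	-4.35	TRUE
cro-mir-3	fungus	33147	UUAGCCUCGAGACUUUGCA	19	-3.74	TRUE	0.27	FALSE	-4.49	TRUE
cro-mir-4	fungus	1994	UCAGCCUCGAGACUUUGCC	19	-2.92	TRUE	0.77	FALSE	-6.01	TRUE
cro-mir-10	fungus	875	UCGGUGGGAUGUUUGAGACU	20	-4.74	TRUE	1.11	FALSE	-3.09	TRUE
cro-mir-11	fungus	955	UAGAGUUUUUGGAGAUGCU	19	-2.42	TRUE	0.49	FALSE	-6.38	TRUE
cro-mir-36	fungus	32160	UCAAACACAAUUAGCGGUC	19	-1.9	TRUE	0.78	FALSE	-6.02	TRUE
cro-mir-73	fungus	48980	UCUGAAGGUCGUGUGUUC	18	5.65	TRUE	-2.69	TRUE	-2.74	TRUE
cro-mir-77	fungus	683	UAUGCCUAGGCUUGUGCGA	19	-3.54	TRUE	-0.93	FALSE	-4.9	TRUE
cro-mir-5	fungus	94	UUGCAAUGAUUUGCAUUUCGC	21	-3.76	TRUE	-2.17	FALSE	-0.88	FALSE
cro-mir-6	fungus	1875	UAGGACUCGAGUAGUUAUAAC	21	-5	TRUE	0.94	FALSE	-2.47	FALSE
cro-mir-9	fungus	447	UCGGACGUAUAUUGACUACUC	21	-3.79	TRUE	-0.95	FALSE	-4.05	FALSE
cro-mir-13	fungus	11099	UUCUUCCUUGAUGCGUCCC	19	-4.62	TRUE	0.11	FALSE	-3.85	FALSE
cro-mir-30	fungus	187	UGCCUGUCUGAGCGUCAUU	19	-2.9	TRUE	2.15	FALSE	1.12	FALSE
cro-mir-74	fungus	460	CACGAUGUCCCGUAUCCGACGU	22	-2.78	TRUE	-0.73	FALSE	-3.21	FALSE
cro-mir-76	fungus	700	UGUUUCUUUGUUUUUGCCU	19	-4.14	TRUE	0.97	FALSE	-2.46	FALSE
mir_12061_x13	wheat	122	UGUAGAUACUCCCUAAGGCUU	21	-1.98	TRUE	1.71	TRUE	0.01	FALSE
mir_18750_x1	wheat	112	UGUAGAUACUCUCUAAGGCUU	21	-2.53	TRUE	2.22	TRUE	0.48	FALSE
mir_16010_x2	wheat	114	UGUAGAUACUCCCUAAGGCU	20	-2.32	TRUE	2.01	TRUE	0.27	FALSE
mir_17532_x1	wheat	118	UGUAGAUACUCCCUAGGGCUU	21	-2.23	TRUE	1.96	TRUE	0.15	FALSE
mir_19460_x1	wheat	125	CACCAACCGGUACUAAUGGGCAUC	24	-2.01	TRUE	2.1	TRUE	1.55	FALSE
mir_13110_x8	wheat	172	UCGGACCAGGCUUCAUUCCUU	21	-1.51	TRUE	1.48	FALSE	0.68	FALSE
mir_18139_x1	wheat	179	CGCCCCACGGUGGGCGCCA	19	1.65	TRUE	-0.8	FALSE	-0.74	FALSE
mir_16988_x1	wheat	296	GUGGAUGAUGAGAUCACAAGUAA	23	1.75	TRUE	-0.52	FALSE	-0.95	FALSE
mir_15432_x2	wheat	140	GCCCCACGGUGGGCGCCA	18	2.34	TRUE	-0.74	FALSE	-1.1	FALSE
mir_13653_x6	wheat	10902	GCCCGUCUAGCUCAGUUGGU	20	0.25	FALSE	-1.68	TRUE	-1.5	TRUE
mir_16507_x1	wheat	83527	CCGACCUUAGCUCAGUUGGU	20	0.32	FALSE	-1.51	TRUE	-1.31	FALSE
mir_18684_x1	wheat	201	GACCUGUAUGGGGCACCA	18	0.69	FALSE	-1.9	TRUE	-0.93	FALSE
mir_19043_x13	wheat	970	AACCUUGUGGUCGUGGGUUC	20	0.95	FALSE	-1.76	TRUE	-1.39	FALSE
mir_15848_x2	wheat	30986	CCCGCCUUGCACCAAGUGAAU	21	-0.36	FALSE	1.54	TRUE	0.83	FALSE
mir_16416_x1	wheat	153	CAUCUCUCCUGUAGAAAUAGGCAC	24	-0.8	FALSE	1.56	TRUE	0.9	FALSE
mir_17663_x1	wheat	8712	UUUCCCGGCUAGUGCACC	18	-0.51	FALSE	-0.44	FALSE	1.58	TRUE
mir_16687_x1	wheat	1322	AACUACAAUCUGAGGCUU	18	-0.71	FALSE	0.11	FALSE	2.42	TRUE
mir_18451_x1	wheat	689	CCACAGGCUUUCUUGAACUG	20	-0.43	FALSE	0.12	FALSE	2.51	TRUE
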