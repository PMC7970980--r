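individual	locus	tissue	method	allele	colony_count	total_major	total_all	printed_frequency	signal
J54	EF1a	hemolymph	cloning	1	1	12	16	0.08	.
J54	EF1a	hemolymph	cloning	D	7	12	16	0.58	.
J54	EF1a	hemolymph	cloning	G	2	12	16	0.17	.
J54	EF1a	hemolymph	cloning	G1	1	12	16	0.08	.
J54	EF1a	hemolymph	cloning	H	1	12	16	0.08	.
J54	EF1a	foot	cloning	1	10	14	16	0.71	.
J54	EF1a	foot	cloning	D	1	14	16	0.07	.
J54	EF1a	foot	cloning	3	3	14	16	0.21	.
J54	CR	hemolymph	cloning	1	16	16	16	1.00	.
J54	CR	foot	direct	3	.	.	.	.	major
J54	COI	hemolymph	direct	1	.	.	.	.	major
J54	COI	hemolymph	direct	3	.	.	.	.	minor
J54	COI	foot	direct	3	.	.	.	.	major
J111	EF1a	hemolymph	cloning	2	2	23	25	0.09	.
J111	EF1a	hemolymph	cloning	4	2	23	25	0.09	.
J111	EF1a	hemolymph	cloning	5	2	23	25	0.09	.
J111	EF1a	hemolymph	cloning	G	11	23	25	0.48	.
J111	EF1a	hemolymph	cloning	G1	1	23	25	0.04	.
J111	EF1a	hemolymph	cloning	H	5	23	25	0.22	.
J111	EF1a	foot	cloning	2	4	16	16	0.25	.
J111	EF1a	foot	cloning	4	10	16	16	0.63	.
J111	EF1a	foot	cloning	H	2	16	16	0.12	.
J111	CR	hemolymph	cloning	4	6	11	16	0.55	.
J111	CR	hemolymph	cloning	2	5	11	16	0.45	.
J111	CR	foot	direct	4	.	.	.	.	major
J111	COI	hemolymph	direct	2	.	.	.	.	major
J111	COI	hemolymph	direct	4	.	.	.	.	minor
J111	COI	foot	direct	4	.	.	.	.	major
J161	EF1a	hemolymph	cloning	D	6	18	24	0.33	.
J161	EF1a	hemolymph	cloning	G	7	18	24	0.39	.
J161	EF1a	hemolymph	cloning	H	5	18	24	0.28	.
J161	EF1a	foot	cloning	6	5	12	16	0.31	.
J161	EF1a	foot	cloning	7	4	12	16	0.25	.
J161	EF1a	foot	cloning	G	2	12	16	0.12	.
J161	EF1a	foot	cloning	H	1	12	16	0.06	.
J161	CR	hemolymph	cloning	1	10	15	16	0.67	.
J161	CR	hemolymph	cloning	1p	5	15	16	0.33	.
J161	CR	foot	direct	5	.	.	.	.	major
J161	COI	hemolymph	direct	1	.	.	.	.	major
J161	COI	hemolymph	direct	5	.	.	.	.	minor
J161	COI	foot	direct	5	.	.	.	.	major
J181	EF1a	hemolymph	cloning	G	24	37	43	0.65	.
J181	EF1a	hemolymph	cloning	H	13	37	43	0.35	.
J181	EF1a	foot	cloning	8	12	16	16	0.75	.
J181	EF1a	foot	cloning	9	4	16	16	0.25	.
J181	CR	hemolymph	cloning	6	3	12	16	0.19	.
J181	CR	hemolymph	cloning	2	9	12	16	0.56	.
J181	CR	foot	direct	6	.	.	.	.	major
J181	COI	hemolymph	direct	2	.	.	.	.	major
J181	COI	hemolymph	direct	6	.	.	.	.	minor
J181	COI	foot	direct	6	.	.	.	.	major
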