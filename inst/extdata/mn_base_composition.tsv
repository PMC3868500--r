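group	position	A	U	C	G
MN	1	0.90	96.61	2.40	0.09
MN	2	83.99	3.11	2.01	10.89
MN	3	10.41	1.42	85.66	2.51
MN	4	3.96	1.95	83.73	10.36
MN	5	6.30	1.28	85.09	7.33
MN	6	1.70	94.87	2.23	1.19
MN	7	7.77	2.78	1.94	87.51
MN	8	8.79	84.02	1.92	5.27
MN	9	88.05	10.10	0.93	0.92
MN	10	5.85	1.18	1.68	91.29
MN	11	86.34	0.46	6.70	6.49
MN	12	88.81	5.31	1.45	4.43
MN	13	1.27	8.18	90.15	0.41
MN	14	0.92	13.78	83.09	2.20
MN	15	1.62	0.75	0.86	96.78
MN	16	86.03	10.53	3.04	0.40
MN	17	92.45	2.44	3.83	1.28
MN	18	2.82	87.87	2.79	6.51
MN	19	5.16	84.35	6.62	3.87
MN	20	1.09	87.95	2.34	8.63
MN	21	3.15	5.76	3.20	87.90
MN	22	0.78	95.56	0.24	3.43
MN	23	5.13	2.72	72.78	19.37
MN	24	0.00	99.37	0.51	0.12
NC	1	10.01	84.27	5.62	0.10
NC	2	22.99	5.07	9.87	62.07
NC	3	42.97	29.38	20.91	6.74
NC	4	27.54	2.84	19.77	49.84
NC	5	34.92	6.37	19.69	39.02
NC	6	29.87	58.16	6.84	5.12
NC	7	35.85	5.20	29.98	28.96
NC	8	38.34	28.22	2.58	30.85
NC	9	27.48	63.04	6.42	3.05
NC	10	32.86	4.33	22.10	40.71
NC	11	20.43	5.49	34.07	40.01
NC	12	44.81	22.61	8.66	23.93
NC	13	6.28	35.38	49.68	8.66
NC	14	3.93	53.36	16.62	26.09
NC	15	27.70	3.42	8.18	60.71
NC	16	31.53	43.49	22.36	2.62
NC	17	51.50	27.04	8.13	13.33
NC	18	12.07	47.97	3.64	36.32
NC	19	32.18	23.90	13.92	29.99
NC	20	24.02	31.37	3.44	41.18
NC	21	26.34	36.24	3.54	33.87
NC	22	4.88	54.75	9.62	30.76
NC	23	8.07	2.10	86.98	2.84
NC	24	21.44	66.17	2.77	9.62
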