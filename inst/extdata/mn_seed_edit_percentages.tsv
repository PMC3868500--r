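mirna	pct_mn	pct_nc	ratio_printed	block
hsa-miR-1	25.59	0.48	53.20	gt1
hsa-miR-542-3p	16.55	0.40	41.80	gt1
hsa-miR-190a	9.09	0.28	32.80	gt1
hsa-miR-30b-5p	19.68	0.75	26.17	gt1
hsa-miR-146a-5p	22.82	1.26	18.13	gt1
hsa-miR-146b-5p	22.07	1.29	17.12	gt1
hsa-miR-128	23.23	1.98	11.73	gt1
hsa-miR-9-5p	24.48	2.17	11.28	gt1
hsa-miR-374b-5p	12.50	1.18	10.62	gt1
hsa-miR-28-5p	12.96	1.24	10.48	gt1
hsa-miR-378b	100.00	99.55	1.00	eq1
hsa-miR-23c	100.00	99.67	1.00	eq1
hsa-miR-378f	100.00	99.72	1.00	eq1
hsa-miR-378h	100.00	99.76	1.00	eq1
hsa-miR-378i	100.00	99.99	1.00	eq1
hsa-miR-1304-3p	100.00	100.00	1.00	eq1
hsa-miR-378g	98.85	99.82	0.99	lt1
hsa-let-7e-5p	94.69	96.50	0.98	lt1
hsa-miR-19a-3p	78.09	81.60	0.96	lt1
hsa-miR-423-5p	0.87	0.92	0.95	lt1
hsa-miR-30e-3p	80.45	85.25	0.94	lt1
hsa-miR-421	10.64	11.48	0.93	lt1
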