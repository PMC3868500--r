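mirna	norm_nc	norm_mn	log2_fc_printed	p_printed	direction	set
hsa-miR-217	191.8607	0.01	-14.22777294	0	down	known
hsa-miR-216a	66.6825	0.01	-12.70309232	5.5967e-245	down	known
hsa-miR-216b	38.1222	0.01	-11.89641592	2.4708e-140	down	known
hsa-miR-95	29.9978	0.01	-11.5506409	1.4472e-110	down	known
hsa-miR-671-5p	22.1858	0.01	-11.11542074	6.07198e-82	down	known
hsa-miR-3653	20.311	0.01	-10.98804541	4.49572e-75	down	known
hsa-miR-1285-3p	14.8739	0.01	-10.53856732	3.75197e-55	down	known
hsa-miR-200c-3p	1181.5995	1.1702	-9.97977026	0	down	known
hsa-miR-29a-5p	9.9993	0.01	-9.9656833	2.72194e-37	down	known
hsa-miR-627	9.7493	0.01	-9.92915478	2.24289e-36	down	known
hsa-miR-425-3p	9.4368	0.01	-9.88215398	3.13127e-35	down	known
hsa-miR-503	8.7493	0.01	-9.77302376	1.03401e-32	down	known
hsa-miR-193a-5p	8.3744	0.01	-9.70984202	2.44579e-31	down	known
hsa-miR-382-5p	7.6869	0.01	-9.58625814	8.07652e-29	down	known
hsa-miR-135b-5p	7.1245	0.01	-9.47664493	9.29106e-27	down	known
hsa-miR-4802-3p	6.812	0.01	-9.41193458	1.29711e-25	down	known
hsa-miR-1246	6.812	0.01	-9.41193458	1.29711e-25	down	known
hsa-miR-500a-5p	6.6245	0.01	-9.37166775	6.30846e-25	down	known
hsa-miR-500b	6.562	0.01	-9.35799181	1.06882e-24	down	known
hsa-miR-5588-5p	5.6246	0.01	-9.1356067	2.90831e-21	down	known
hsa-miR-486-5p	26.5605	13344.793	8.97277891	0	up	known
hsa-miR-208b	0.01	4.8609	8.92507964	9.79541e-22	up	known
hsa-miR-133a	0.6874	306.0547	8.79842396	0	up	known
hsa-miR-449a	0.01	4.1407	8.69373087	1.23214e-18	up	known
hsa-miR-195-3p	0.01	2.2504	7.81403765	1.68736e-10	up	known
hsa-miR-449c-5p	0.01	1.9804	7.62964804	2.45229e-09	up	known
hsa-miR-133b	0.0625	9.9918	7.3207446	5.40583e-42	up	known
hsa-miR-204-5p	92.2431	2212.9552	4.58438944	0	up	known
hsa-miR-410	0.25	5.3109	4.40895636	9.13765e-19	up	known
hsa-miR-21-3p	4.1872	78.134	4.22189274	5.5898e-249	up	known
hsa-miR-10b-5p	55198.7661	628948.7014	3.51023443	0	up	known
hsa-miR-19a-3p	5.1871	51.3092	3.30621744	6.9257e-134	up	known
hsa-miR-4661-5p	0.125	1.1702	3.22675512	0.000345083	up	known
hsa-miR-199b-5p	1.5624	13.8625	3.1493517	1.00921e-35	up	known
hsa-let-7i-5p	248.6065	2045.6153	3.04059893	0	up	known
hsa-miR-144-3p	0.9999	8.1915	3.03427193	5.66076e-21	up	known
hsa-miR-486-3p	0.5	3.7807	2.91865338	4.6769e-10	up	known
hsa-miR-19b-3p	24.4357	181.8325	2.89554775	0	up	known
hsa-miR-941	1.9374	12.7823	2.7219537	1.49032e-28	up	known
hsa-miR-1468	1.4999	9.0916	2.59966789	9.12913e-20	up	known
novel_miR_82	1.1249	0.01	-6.81365294	8.92e-05	down	novel
novel_miR_98	1.3749	0.01	-7.10318289	1.08e-05	down	novel
novel_miR_89	1.6874	0.01	-7.3986582	7.75e-07	down	novel
novel_miR_84	1.7499	0.01	-7.45112866	4.58e-07	down	novel
novel_miR_152	0.01	1.6203	7.34011714	8.70e-08	up	novel
novel_miR_15	0.01	9.2717	9.85669008	1.01e-40	up	novel
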