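rsid	position	allele_a	allele_b	maf	hwe_p	or	or_low	or_high	p_assoc	beta	starred
rs17728461	chr22:30598552	C	G	0.17	0.70	1.37	1.24	1.51	8.50E-10	0.0535	FALSE
rs465498	chr5:1325803	A	G	0.16	0.11	0.75	0.67	0.84	6.83E-07	0.0523	TRUE
rs753955	chr13:24293859	A	G	0.29	0.76	1.23	1.13	1.35	1.33E-06	0.0482	FALSE
rs2895680	chr5:146644115	T	C	0.28	0.62	1.21	1.11	1.32	1.04E-05	0.0415	FALSE
rs12296850	chr12:100820085	A	G	0.25	0.14	0.82	0.75	0.90	3.09E-05	0.0402	TRUE
rs4488809	chr3:189356261	C	T	0.47	1.00	1.21	1.12	1.31	2.39E-06	0.0375	FALSE
rs2736100	chr5:1286516	A	C	0.41	0.30	1.20	1.11	1.30	8.84E-06	0.0374	FALSE
rs9439519	chr1:5364634	T	C	0.27	0.93	1.18	1.08	1.29	2.18E-04	0.0361	FALSE
rs383362	chr16:79245820	G	T	0.15	0.62	1.17	1.05	1.30	3.97E-03	0.0357	FALSE
rs6573	chr1:112255389	C	A	0.13	0.47	0.82	0.73	0.93	1.27E-03	0.0346	TRUE
rs247008	chr5:131447104	G	A	0.47	0.06	0.83	0.77	0.90	6.27E-06	0.0343	TRUE
rs4809957	chr20:52771171	G	A	0.35	0.20	1.18	1.09	1.28	7.11E-05	0.0341	FALSE
rs4246215	chr11:61564299	G	T	0.41	0.85	0.82	0.76	0.89	2.04E-06	0.0335	TRUE
rs1663689	chr10:9025195	T	C	0.42	0.97	0.85	0.79	0.92	8.03E-05	0.0313	TRUE
rs7086803	chr10:114498476	G	A	0.28	0.62	1.16	1.06	1.26	1.06E-03	0.0297	FALSE
rs4083914	chr6:153427706	G	C	0.14	0.19	1.16	1.04	1.29	7.36E-03	0.0293	FALSE
rs2286455	chr4:16020162	C	T	0.23	0.14	1.15	1.05	1.26	3.70E-03	0.0284	TRUE
rs3764340	chr16:78466437	C	G	0.07	1.00	1.20	1.04	1.39	0.012	0.0283	FALSE
rs36600	chr22:30337586	C	T	0.09	0.82	1.39	1.22	1.58	8.38E-07	0.0281	FALSE
rs842461	chr3:195535614	T	G	0.27	0.27	1.18	1.09	1.29	1.19E-04	0.0253	FALSE
rs2285053	chr16:55512377	C	T	0.24	0.25	0.90	0.82	0.99	0.029	0.0247	FALSE
rs2131877	chr3:194858374	A	G	0.44	0.07	0.91	0.84	0.99	0.025	0.0240	TRUE
rs1801133	chr1:11856378	G	A	0.44	0.36	1.16	1.07	1.26	1.76E-04	0.0232	FALSE
rs3866958	chr17:19281006	C	A	0.15	0.44	0.87	0.78	0.97	0.015	0.0225	TRUE
rs1800625	chr6:32152442	A	G	0.13	0.75	1.12	1.00	1.26	0.046	0.0218	FALSE
rs9387478	chr6:117786180	C	A	0.5	0.86	0.91	0.84	0.98	0.013	0.0216	TRUE
rs743572	chr10:104597152	G	A	0.4	1.00	1.09	1.01	1.18	0.026	0.0209	FALSE
rs4291	chr17:61554194	A	T	0.37	0.08	1.10	1.02	1.20	0.015	0.0208	FALSE
rs10845498	chr12:12394574	A	G	0.18	0.11	0.89	0.80	0.98	0.023	0.0202	TRUE
rs7326277	chr13:28876214	T	C	0.33	0.65	0.91	0.84	0.99	0.038	0.0189	TRUE
rs931127	chr11:65405300	G	A	0.48	0.08	0.91	0.84	0.99	0.028	0.0189	TRUE
rs2016520	chr6:35378778	T	C	0.27	0.47	1.10	1.01	1.20	0.037	0.0161	FALSE
rs25406	chr20:5099636	G	A	0.36	0.56	0.91	0.84	0.99	0.025	0.0158	TRUE
rs2240688	chr4:15970349	T	G	0.26	0.58	0.91	0.83	1.00	0.040	0.0134	TRUE
rs34843907	chr6:32610059	G	T	0.33	0.39	1.09	1.00	1.18	0.041	0.0121	FALSE
rs2070600	chr6:32151443	C	T	0.23	0.29	0.91	0.83	1.00	0.046	0.0109	TRUE
rs189037	chr11:108093833	G	A	0.43	0.07	1.08	1.00	1.18	0.049	0.0080	FALSE
rs3817963	chr6:32368087	T	C	0.25	0.07	1.08	0.99	1.18	0.078	0.0075	FALSE
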