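table	gene	section	fc_p2	fc_p3	fc_p4	fc_p5	fc_p6	fc_p9	fc_p10	fc_p11	fc_p12	avg_fc	p_value	footnote_exclude	all_absent
T1	ENO2	over	52.71	80.66	10.03	7.57	22.03	46.03	9.81	25.29	50.01	33.79	3.53E-06		FALSE
T1	HK2	over	55.80	10.81	6.19	4.68	23.24	4.68	30.80	8.66	43.06	20.88	3.52E-05		FALSE
T1	PFKP	over	13.30	5.84	4.69	6.85	8.86	8.85	6.74	9.76	7.11	8.00	4.23E-08		FALSE
T1	SLC2A3	over	5.89	6.52	4.55	5.89	3.10	11.90	13.48	3.05	3.37	6.42	1.30E-05		FALSE
T1	ALDOC	over	5.75	5.46	2.03	5.38	1.27	4.22	4.48	1.36	1.43	3.49	1.19E-03		FALSE
T1	PKM	over	6.06	2.32	2.41	2.06	3.18	3.15	1.22	3.06	5.23	3.19	1.72E-04		FALSE
T1	PFKFB4	over	9.27	1.39	1.90	2.32	2.33	3.15	1.86	1.80	2.96	3.00	1.00E-03		FALSE
T1	SLC2A1	over	2.15	1.49	1.64	1.29	1.80	3.99	1.17	3.72	3.38	2.29	1.58E-03		FALSE
T1	HK1	over	2.69	2.33	1.47	1.45	2.78	2.58	-1.02	2.68	3.50	2.27	5.82E-04		FALSE
T1	ALDOA	over	2.38	2.73	1.62	1.81	2.21	2.33	1.66	2.19	2.79	2.19	2.94E-06		FALSE
T1	PGAM1	over	2.95	2.11	1.56	2.23	2.08	2.04	2.19	2.03	1.75	2.10	1.51E-06		FALSE
T1	ALDOB	under	-82.38	-23.11	-35.40	-17.78	-10.01	-13.62	-135.83	-40.16	-658.50	-43.75	2.55E-05		FALSE
T1	PKLR	under	-10.99	A/A	-12.13	A/A	A/A	A/A	A/A	-4.63	A/A	-8.51	1.13E-04		FALSE
T1	PFKFB2	under	-3.96	-5.78	-4.27	-8.35	-7.19	-8.58	-2.78	-3.39	-4.27	-5.02	2.18E-06		FALSE
T1	VHL	under	A/A	A/A	A/A	-3.43	-5.45	A/A	-3.06	A/A	-1.44	-3.01	3.96E-04		FALSE
T2	PSAT1	none	-28.85	-36.43	-16.73	-61.88	-100.44	-20.74	-18.36	-6.66	-3.38	-21.39	2.20E-05		FALSE
T2	PHGDH	none	-1.12	-12.13	-2.48	-2.38	-2.84	-7.58	-2.15	-3.30	-16.53	-3.89	1.78E-03		FALSE
T2	SHMT1	none	-4.25	-2.72	-3.48	-2.50	-8.51	-2.20	-2.20	-4.71	-3.71	-3.47	2.73E-05		FALSE
T2	PSPH	none	-1.22	2.00	1.12	1.72	-1.26	-2.65	-1.04	-1.27	-3.05	-1.17	4.45E-01		FALSE
T3	G6PC	none	-31.66	-19.47	-304.97	-7.26	-21.32	-69.94	-99.07	-147.53	-127.90	-53.84	8.38E-06		FALSE
T3	ALDOB	none	-82.38	-23.11	-35.40	-17.78	-10.01	-13.62	-135.83	-40.16	-658.50	-43.75	2.55E-05		FALSE
T3	PCK1	none	-11.87	-10.50	-15.28	-2.88	-13.13	-5.94	-4.52	-21.55	-1086.66	-8.96	1.67E-05	p12	FALSE
T3	FBP1	none	-11.74	-12.17	-7.21	-7.52	-6.73	-9.92	-3.97	-9.55	-11.61	-8.48	1.04E-07		FALSE
T3	PC	none	-8.81	A/A	A/A	-19.56	-5.46	-7.18	A/A	-5.34	-7.81	-8.10	2.18E-05		FALSE
T3	PCK2	none	-8.92	-8.76	-7.94	-6.23	-10.36	-7.33	-2.02	-8.56	-12.93	-7.39	3.24E-06		FALSE
T3	KHK	none	-1.88	-5.93	-2.61	-2.04	-2.91	-3.37	-1.42	-3.07	-3.57	-2.75	8.61E-05		FALSE
T3	MDH1	none	-1.32	-2.53	-1.45	-1.98	-2.63	-2.19	-1.38	-1.59	-1.87	-1.83	1.14E-04		FALSE
T3	G6PC2	none	-1.61	-1.45	-1.20	A/A	A/A	-1.08	A/A	-1.37	-1.09	-1.29	1.47E-02		FALSE
T3	G6PC3	none	-1.84	-1.45	-1.37	-1.25	-1.78	-1.42	1.13	-1.03	1.26	-1.27	4.17E-02		FALSE
T3	SLC2A5	none	1.42	1.34	-4.36	1.39	-1.16	1.08	-1.51	-1.24	-1.19	-1.16	4.41E-01		FALSE
T4	PDK1	over	16.23	17.82	3.90	5.37	6.22	9.76	6.17	9.34	15.34	10.02	2.07E-06		FALSE
T4	SLC16A3	over	7.83	6.55	4.92	3.74	9.35	8.46	2.55	10.06	10.35	7.09	2.99E-06		FALSE
T4	SLC16A1	over	4.19	5.10	2.99	2.11	2.10	1.04	5.24	5.73	3.50	3.56	2.68E-04		FALSE
T4	LDHA	over	2.99	2.84	3.21	2.72	2.99	2.61	3.23	2.35	4.13	3.01	3.34E-08		FALSE
T4	SUCLG1	under	-4.57	-5.25	-4.71	-5.26	-5.22	-4.41	-2.62	-5.85	-6.42	-4.80	7.88E-08		FALSE
T4	PDHB	under	-1.76	-3.69	-1.59	-2.49	-3.63	-2.16	-2.03	-2.89	-4.51	-2.59	4.65E-05		FALSE
T4	OGDH	under	-2.14	-1.43	-1.44	-3.24	-1.77	-3.23	-5.35	-1.68	-3.64	-2.40	5.03E-04		FALSE
T4	PDHA1	under	-1.53	-2.65	-4.50	-1.35	-3.19	-2.18	-2.37	-2.85	-2.09	-2.38	1.04E-04		FALSE
T4	SUCLG2	under	-1.66	-2.84	-2.13	-1.72	-3.00	-2.92	-1.92	-1.98	-3.14	-2.30	9.97E-06		FALSE
T4	DLST	under	1.21	-2.03	-1.49	-2.51	-2.06	-4.19	-1.63	-2.62	-3.11	-2.08	1.60E-03		FALSE
T4	FH	under	-1.65	-3.89	-1.62	-2.13	-2.21	-2.60	-1.94	-1.32	-1.77	-2.03	1.48E-04		FALSE
T4	PDK4	unchanged	2.18	1.31	1.96	1.37	-1.71	1.98	2.11	1.67	-1.02	1.46	3.01E-02		FALSE
T4	LDHB	unchanged	-2.27	-1.35	-1.84	-2.05	-3.05	-1.92	-1.74	-1.98	-1.18	-1.87	1.43E-04		FALSE
T4	IDH2	unchanged	1.29	-1.86	-2.65	-1.98	-2.21	-3.29	-2.49	-1.44	-1.38	-1.86	2.51E-03		FALSE
T4	PDK2	unchanged	-1.33	-1.57	-1.97	-1.56	-1.29	-1.79	-1.62	-1.75	-3.31	-1.73	3.56E-04		FALSE
T4	ACO2	unchanged	-1.23	-2.03	-2.28	-1.66	-1.24	-3.15	-1.45	-1.47	-1.78	-1.73	6.57E-04		FALSE
T4	SDHD	unchanged	-2.31	-1.11	-1.27	-1.21	-1.71	-1.82	-1.37	-1.80	-3.42	-1.67	2.49E-03		FALSE
T4	DLAT	unchanged	1.05	-2.46	-1.66	2.73	-1.65	-2.07	-1.83	-1.67	-3.46	-1.55	7.51E-02		FALSE
T4	SDHB	unchanged	-1.48	-1.99	-1.49	-1.23	-1.46	-1.78	-1.02	-2.09	-1.58	-1.53	4.53E-04		FALSE
T4	SDHC	unchanged	1.72	-1.41	-1.78	-2.08	-1.03	-2.39	-1.74	-1.60	-2.05	-1.52	2.08E-02		FALSE
T4	IDH3B	unchanged	-1.51	-1.20	-1.98	-1.23	-4.85	-1.23	-1.13	1.05	-1.33	-1.50	3.74E-02		FALSE
T4	DLD	unchanged	-1.24	-1.16	-1.94	-1.03	-1.64	-2.18	-1.23	-1.46	-1.85	-1.48	1.93E-03		FALSE
T4	SUCLA2	unchanged	-1.26	1.19	-1.31	1.09	-1.37	-1.32	-1.23	-2.23	-4.15	-1.44	5.43E-02		FALSE
T4	MDH2	unchanged	-1.05	-1.07	-1.30	-1.48	-1.40	-1.52	-2.07	-1.49	-1.15	-1.36	2.32E-03		FALSE
T4	SDHA	unchanged	1.01	1.14	-1.87	-1.88	1.10	-1.71	1.00	-1.66	-1.68	-1.33	3.25E-02		FALSE
T4	IDH3G	unchanged	-1.21	-1.17	-1.28	-1.20	1.10	-1.47	-2.07	-1.34	-1.24	-1.29	8.11E-03		FALSE
T4	CS	unchanged	-1.46	1.12	-1.52	-1.26	-1.34	-1.06	1.04	-1.02	1.22	-1.12	1.54E-01		FALSE
T4	PDHX	unchanged	1.63	-1.02	-1.21	-1.12	-1.60	-1.23	-1.11	-1.27	-1.20	-1.12	2.17E-01		FALSE
T4	IDH3A	unchanged	1.89	-1.09	-1.81	-1.42	1.28	1.04	-1.44	-1.42	1.56	-1.04	7.70E-01		FALSE
T4	PDK3	unchanged	1.29	-1.36	1.11	-1.08	-1.52	1.47	-1.02	-1.22	1.10	-1.02	8.21E-01		FALSE
T5	ACLY	over	2.15	3.23	1.62	3.07	2.44	1.97	3.13	1.87	3.54	2.56	1.05E-05		FALSE
T5	ACO1	under	-2.98	-2.83	-2.60	-2.59	-2.99	-5.76	-1.53	-2.13	-2.88	-2.76	2.38E-05		FALSE
T5	GLS	under	-2.81	-1.90	-3.53	-2.49	-4.43	-2.45	-1.54	-1.98	-3.71	-2.62	3.28E-05		FALSE
T5	GLS2	under	-1.86	-3.98	-1.40	-7.23	-4.00	-2.63	-2.27	1.28	-3.18	-2.54	2.65E-03		TRUE
T5	ACACB	under	-2.29	-2.88	-2.28	-3.10	-4.20	1.10	-1.89	-3.43	-1.79	-2.32	5.08E-04		FALSE
T5	IDH1	under	-2.69	-2.43	-2.21	-2.95	-3.58	-1.68	-1.22	-1.67	-2.30	-2.20	9.61E-05		FALSE
T5	GOT1	under	-1.09	-1.72	-3.16	-1.55	-3.59	-2.92	-1.27	-1.86	-2.75	-2.04	1.02E-03		FALSE
T5	ME2	unchanged	1.83	1.45	1.40	1.62	1.53	1.09	1.18	1.25	2.20	1.47	7.54E-04		FALSE
T5	GOT2	unchanged	-1.25	-1.18	-2.32	-1.66	-2.46	-2.28	-2.66	-1.86	-1.92	-1.89	1.76E-04		FALSE
T5	GLUD1	unchanged	-1.57	-1.45	-1.02	-1.39	1.57	-4.25	-2.15	1.07	-2.89	-1.55	5.61E-02		FALSE
T5	FASN	unchanged	-1.22	-1.57	-1.09	-1.61	1.32	-1.28	-2.05	1.79	1.11	-1.14	3.48E-01		FALSE
T5	ME1	unchanged	-1.40	-1.01	1.94	1.25	-2.32	-1.54	-1.34	2.68	-1.21	-1.03	9.00E-01		FALSE
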