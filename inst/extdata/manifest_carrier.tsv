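sample_id	cohort	clin_gene	clin_chrom	clin_pos	clin_ref	clin_alt	clin_category
BRCA1.1	BRCA1	BRCA1	13	1122619	T	A	cnv
BRCA1.2	BRCA1	BRCA1	13	1122622	T	A	ivs
BRCA1.3	BRCA1	BRCA1	13	1122625	T	A	cnv
BRCA1.4	BRCA1	BRCA1	13	1122628	T	A	ivs
BRCA1.5	BRCA1	BRCA1	13	1122631	T	A	cnv
BRCA1.6	BRCA1	BRCA1	13	1122634	T	A	ivs
BRCA1.7	BRCA1	BRCA1	13	1122637	T	A	cnv
BRCA1.8	BRCA1	BRCA1	13	1122640	T	A	ivs
BRCA1.9	BRCA1	BRCA1	13	1122643	T	A	cnv
BRCA1.10	BRCA1	BRCA1	13	1122646	T	A	ivs
BRCA1.11	BRCA1	BRCA1	13	1122649	T	A	cnv
BRCA1.12	BRCA1	BRCA1	13	1122652	T	A	ivs
BRCA1.13	BRCA1	BRCA1	13	1122655	T	A	cnv
BRCA1.14	BRCA1	BRCA1	13	1122658	TG	T	indel
BRCA1.15	BRCA1	BRCA1	13	1122661	TG	T	indel
BRCA1.16	BRCA1	BRCA1	13	1122664	TG	T	indel
BRCA1.17	BRCA1	BRCA1	13	1122667	TG	T	indel
BRCA1.18	BRCA1	BRCA1	13	1122670	TG	T	indel
BRCA1.19	BRCA1	BRCA1	13	1122673	TG	T	indel
BRCA1.20	BRCA1	BRCA1	13	1122676	TG	T	indel
BRCA1.21	BRCA1	BRCA1	13	1122679	T	A	snv
BRCA1.22	BRCA1	BRCA1	13	1122682	TG	T	indel
BRCA1.23	BRCA1	BRCA1	13	1122685	TG	T	indel
BRCA1.24	BRCA1	BRCA1	13	1122688	TG	T	indel
BRCA1.25	BRCA1	BRCA1	13	1122691	TG	T	indel
BRCA1.26	BRCA1	BRCA1	13	1122694	TG	T	indel
BRCA1.27	BRCA1	BRCA1	13	1122697	TG	T	indel
BRCA1.28	BRCA1	BRCA1	13	1122700	TG	T	indel
BRCA1.29	BRCA1	BRCA1	13	1122703	TG	T	indel
BRCA1.30	BRCA1	BRCA1	13	1122706	TG	T	indel
BRCA1.31	BRCA1	BRCA1	13	1122709	TG	T	indel
BRCA1.32	BRCA1	BRCA1	13	1122712	TG	T	indel
BRCA1.33	BRCA1	BRCA1	13	1122715	TG	T	indel
BRCA1.34	BRCA1	BRCA1	13	1122718	TG	T	indel
BRCA1.35	BRCA1	BRCA1	13	1122721	TG	T	indel
BRCA1.36	BRCA1	BRCA1	13	1122724	TG	T	indel
BRCA1.37	BRCA1	BRCA1	13	1122727	TG	T	indel
BRCA1.38	BRCA1	BRCA1	13	1122730	TG	T	indel
BRCA1.39	BRCA1	BRCA1	13	1122733	TG	T	indel
BRCA1.40	BRCA1	BRCA1	13	1122736	TG	T	indel
BRCA1.41	BRCA1	BRCA1	13	1122739	TG	T	indel
BRCA1.42	BRCA1	BRCA1	13	1122742	T	A	snv
BRCA1.43	BRCA1	BRCA1	13	1122745	T	A	snv
BRCA1.44	BRCA1	BRCA1	13	1122748	T	A	snv
BRCA1.45	BRCA1	BRCA1	13	1122751	T	A	snv
BRCA1.46	BRCA1	BRCA1	13	1122754	T	A	snv
BRCA1.47	BRCA1	BRCA1	13	1122757	T	A	snv
BRCA1.48	BRCA1	BRCA1	13	1122760	T	A	snv
BRCA1.49	BRCA1	BRCA1	13	1122763	T	A	snv
BRCA1.50	BRCA1	BRCA1	13	1122766	T	A	snv
BRCA1.51	BRCA1	BRCA1	13	1122769	T	A	snv
BRCA1.52	BRCA1	BRCA1	13	1122772	T	A	snv
BRCA1.53	BRCA1	BRCA1	13	1122775	T	A	snv
BRCA1.54	BRCA1	BRCA1	13	1122778	T	A	snv
BRCA1.55	BRCA1	BRCA1	13	1122781	T	A	snv
BRCA1.56	BRCA1	BRCA1	13	1122784	T	A	snv
BRCA1.57	BRCA1	BRCA1	13	1122787	T	A	snv
BRCA1.58	BRCA1	BRCA1	13	1122790	T	A	snv
BRCA1.59	BRCA1	BRCA1	13	1122793	T	A	snv
BRCA1.60	BRCA1	BRCA1	13	1122796	T	A	snv
BRCA1.61	BRCA1	BRCA1	13	1122799	T	A	snv
BRCA1.62	BRCA1	BRCA1	13	1122802	T	A	snv
BRCA1.63	BRCA1	BRCA1	13	1122805	T	A	snv
BRCA1.64	BRCA1	BRCA1	13	1122808	T	A	snv
BRCA1.65	BRCA1	BRCA1	13	1122811	T	A	snv
BRCA1.66	BRCA1	BRCA1	13	1122814	T	A	snv
BRCA1.67	BRCA1	BRCA1	13	1122817	T	A	snv
BRCA1.68	BRCA1	BRCA1	13	1122820	T	A	snv
BRCA1.69	BRCA1	BRCA1	13	1122823	T	A	snv
BRCA1.70	BRCA1	BRCA1	13	1122826	T	A	snv
BRCA1.71	BRCA1	BRCA1	13	1122829	T	A	snv
BRCA1.72	BRCA1	BRCA1	13	1122832	T	A	snv
BRCA1.73	BRCA1	BRCA1	13	1122835	T	A	snv
BRCA1.74	BRCA1	BRCA1	13	1122838	T	A	snv
BRCA1.75	BRCA1	BRCA1	13	1122841	T	A	snv
BRCA1.76	BRCA1	BRCA1	13	1122844	T	A	snv
BRCA1.77	BRCA1	BRCA1	13	1122847	T	A	snv
BRCA1.78	BRCA1	BRCA1	13	1122850	T	A	snv
BRCA1.79	BRCA1	BRCA1	13	1122853	T	A	snv
BRCA1.80	BRCA1	BRCA1	13	1122856	T	A	snv
BRCA1.81	BRCA1	BRCA1	13	1122859	T	A	snv
BRCA1.82	BRCA1	BRCA1	13	1122862	T	A	snv
BRCA1.83	BRCA1	BRCA1	13	1122865	T	A	snv
BRCA1.84	BRCA1	BRCA1	13	1122868	T	A	snv
BRCA1.85	BRCA1	BRCA1	13	1122871	T	A	snv
BRCA1.86	BRCA1	BRCA1	13	1122874	T	A	snv
BRCA1.87	BRCA1	BRCA1	13	1122877	T	A	snv
BRCA1.88	BRCA1	BRCA1	13	1122880	T	A	snv
BRCA2.1	BRCA2	BRCA2	18	1123274	TG	T	indel
BRCA2.2	BRCA2	BRCA2	18	1123277	TG	T	indel
BRCA2.3	BRCA2	BRCA2	18	1123280	TG	T	indel
BRCA2.4	BRCA2	BRCA2	18	1123283	TG	T	indel
BRCA2.5	BRCA2	BRCA2	18	1123286	TG	T	indel
BRCA2.6	BRCA2	BRCA2	18	1123289	TG	T	indel
BRCA2.7	BRCA2	BRCA2	18	1123292	TG	T	indel
BRCA2.8	BRCA2	BRCA2	18	1123295	TG	T	indel
BRCA2.9	BRCA2	BRCA2	18	1123298	TG	T	indel
BRCA2.10	BRCA2	BRCA2	18	1123301	T	A	snv
BRCA2.11	BRCA2	BRCA2	18	1123304	TG	T	indel
BRCA2.12	BRCA2	BRCA2	18	1123307	TG	T	indel
BRCA2.13	BRCA2	BRCA2	18	1123310	TG	T	indel
BRCA2.14	BRCA2	BRCA2	18	1123313	TG	T	indel
BRCA2.15	BRCA2	BRCA2	18	1123316	TG	T	indel
BRCA2.16	BRCA2	BRCA2	18	1123319	TG	T	indel
BRCA2.17	BRCA2	BRCA2	18	1123322	TG	T	indel
BRCA2.18	BRCA2	BRCA2	18	1123325	TG	T	indel
BRCA2.19	BRCA2	BRCA2	18	1123328	TG	T	indel
BRCA2.20	BRCA2	BRCA2	18	1123331	TG	T	indel
BRCA2.21	BRCA2	BRCA2	18	1123334	TG	T	indel
BRCA2.22	BRCA2	BRCA2	18	1123337	TG	T	indel
BRCA2.23	BRCA2	BRCA2	18	1123340	TG	T	indel
BRCA2.24	BRCA2	BRCA2	18	1123343	TG	T	indel
BRCA2.25	BRCA2	BRCA2	18	1123346	TG	T	indel
BRCA2.26	BRCA2	BRCA2	18	1123349	TG	T	indel
BRCA2.27	BRCA2	BRCA2	18	1123352	TG	T	indel
BRCA2.28	BRCA2	BRCA2	18	1123355	TG	T	indel
BRCA2.29	BRCA2	BRCA2	18	1123358	TG	T	indel
BRCA2.30	BRCA2	BRCA2	18	1123361	TG	T	indel
BRCA2.31	BRCA2	BRCA2	18	1123364	TG	T	indel
BRCA2.32	BRCA2	BRCA2	18	1123367	TG	T	indel
BRCA2.33	BRCA2	BRCA2	18	1123370	TG	T	indel
BRCA2.34	BRCA2	BRCA2	18	1123373	TG	T	indel
BRCA2.35	BRCA2	BRCA2	18	1123376	TG	T	indel
BRCA2.36	BRCA2	BRCA2	18	1123379	T	A	snv
BRCA2.37	BRCA2	BRCA2	18	1123382	T	A	snv
BRCA2.38	BRCA2	BRCA2	18	1123385	T	A	snv
BRCA2.39	BRCA2	BRCA2	18	1123388	T	A	snv
BRCA2.40	BRCA2	BRCA2	18	1123391	T	A	snv
BRCA2.41	BRCA2	BRCA2	18	1123394	T	A	snv
BRCA2.42	BRCA2	BRCA2	18	1123397	T	A	snv
BRCA2.43	BRCA2	BRCA2	18	1123400	T	A	snv
BRCA2.44	BRCA2	BRCA2	18	1123403	T	A	snv
BRCA2.45	BRCA2	BRCA2	18	1123406	T	A	snv
BRCA2.46	BRCA2	BRCA2	18	1123409	T	A	snv
BRCA2.47	BRCA2	BRCA2	18	1123412	T	A	snv
BRCA2.48	BRCA2	BRCA2	18	1123415	T	A	snv
BRCA2.49	BRCA2	BRCA2	18	1123418	T	A	snv
BRCA2.50	BRCA2	BRCA2	18	1123421	T	A	snv
BRCA2.51	BRCA2	BRCA2	18	1123424	T	A	snv
BRCA2.52	BRCA2	BRCA2	18	1123427	T	A	snv
BRCA2.53	BRCA2	BRCA2	18	1123430	T	A	snv
BRCA2.54	BRCA2	BRCA2	18	1123433	T	A	snv
BRCA2.55	BRCA2	BRCA2	18	1123436	T	A	snv
BRCA2.56	BRCA2	BRCA2	18	1123439	T	A	snv
BRCA2.57	BRCA2	BRCA2	18	1123442	T	A	snv
BRCA2.58	BRCA2	BRCA2	18	1123445	T	A	snv
BRCA2.59	BRCA2	BRCA2	18	1123448	T	A	snv
BRCA2.60	BRCA2	BRCA2	18	1123451	T	A	snv
BRCA2.61	BRCA2	BRCA2	18	1123454	T	A	snv
BRCA2.62	BRCA2	BRCA2	18	1123457	T	A	snv
BRCA2.63	BRCA2	BRCA2	18	1123460	T	A	snv
BRCA2.64	BRCA2	BRCA2	18	1123463	T	A	snv
BRCA2.65	BRCA2	BRCA2	18	1123466	T	A	snv
BRCA2.66	BRCA2	BRCA2	18	1123469	T	A	snv
BRCA2.67	BRCA2	BRCA2	18	1123472	T	A	snv
BRCA2.68	BRCA2	BRCA2	18	1123475	T	A	snv
BRCA2.69	BRCA2	BRCA2	18	1123478	T	A	snv
BRCA2.70	BRCA2	BRCA2	18	1123481	T	A	snv
BRCA2.71	BRCA2	BRCA2	18	1123484	T	A	snv
BRCA2.72	BRCA2	BRCA2	18	1123487	T	A	snv
BRCA2.73	BRCA2	BRCA2	18	1123490	T	A	snv
BRCA2.74	BRCA2	BRCA2	18	1123493	T	A	snv
BRCA2.75	BRCA2	BRCA2	18	1123496	T	A	snv
BRCA2.76	BRCA2	BRCA2	18	1123499	T	A	snv
BRCA2.77	BRCA2	BRCA2	18	1123502	T	A	snv
BRCA2.78	BRCA2	BRCA2	18	1123505	T	A	snv
BRCA2.79	BRCA2	BRCA2	18	1123508	T	A	snv
BRCA2.80	BRCA2	BRCA2	18	1123511	T	A	snv
BRCA2.81	BRCA2	BRCA2	18	1123514	T	A	snv
BRCA2.82	BRCA2	BRCA2	18	1123517	T	A	snv
BRCA2.83	BRCA2	BRCA2	18	1123520	T	A	snv
BRCA2.84	BRCA2	BRCA2	18	1123523	T	A	snv
BRCA2.85	BRCA2	BRCA2	18	1123526	T	A	snv
BRCA2.86	BRCA2	BRCA2	18	1123529	T	A	snv
BRCA2.87	BRCA2	BRCA2	18	1123532	T	A	snv
BRCA2.88	BRCA2	BRCA2	18	1123535	T	A	snv
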