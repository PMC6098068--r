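ptt	gender	gender_inferred	tagging_location	deploy_date	first_loc_date	last_loc_date	duration_days	transmitting_days	distance_km	n_patches	search_days_total	max_patch_days	min_patch_days	search_days_au_ec	search_days_ts	search_days_ant
88718	Male	FALSE	AU-Eden	2008-10-24	2008-10-24	2009-01-24	93	92	5776	3	50	19	14	36	0	14
88723	Unknown	FALSE	AU-Eden	2008-10-24	2008-10-24	2009-01-13	82	81	5848	2	26	15	11	0	11	15
88732	Male	FALSE	AU-Eden	2008-10-24	2008-10-24	2008-11-27	35	35	2571	1	8	8	8	0	8	0
88733	Female	TRUE	AU-Eden	2008-10-24	2008-10-24	2008-12-04	42	42	4042	0	NA	NA	NA	NA	NA	NA
88735	Male	FALSE	AU-Eden	2008-10-24	2008-10-24	2008-12-01	39	38	1529	3	30	14	5	30	0	0
88743	Male	FALSE	AU-Eden	2008-10-24	2008-10-24	2008-11-05	13	13	583	0	NA	NA	NA	NA	NA	NA
88746	Male	FALSE	AU-Eden	2008-10-24	2008-10-24	2008-11-12	20	20	1720	0	NA	NA	NA	NA	NA	NA
88725	Male	FALSE	AU-Eden	2008-10-25	2008-10-25	2009-01-13	81	80	5520	3	61	29	15	29	0	32
88744	Male	FALSE	AU-Eden	2008-10-25	2008-10-25	2008-10-27	3	3	103	0	NA	NA	NA	NA	NA	NA
88745	Male	FALSE	AU-Eden	2008-10-25	2008-10-25	2008-11-12	19	14	1429	0	NA	NA	NA	NA	NA	NA
88738	Male	FALSE	AU-Eden	2008-10-27	2008-10-27	2008-12-23	58	58	4639	4	29	17	3	7	0	22
88722	Female	FALSE	AU-Eden	2008-10-28	2008-10-28	2008-11-16	20	20	1329	1	13	13	13	13	0	0
88729	Female	FALSE	AU-Eden	2008-10-29	2008-10-29	2009-02-03	98	97	7202	3	56	37	3	3	0	53
88717	Female	TRUE	AU-Eden	2008-10-31	2008-10-31	2008-11-29	30	30	2025	1	8	8	8	0	8	0
88728	Female	TRUE	AU-Eden	2008-10-31	2008-10-31	2009-02-01	94	93	6312	3	37	16	5	0	0	37
88741	Female	FALSE	AU-Eden	2008-11-01	2008-11-01	2009-04-04	155	153	10324	6	93	28	4	4	0	89
53348	Male	FALSE	ANT	2010-02-21	2010-02-21	2010-03-24	32	26	1566	1	20	20	20	0	0	20
53736	Female	FALSE	ANT	2010-02-21	2010-02-17	2010-04-06	49	39	2486	1	9	9	9	0	0	9
96385	Female	FALSE	ANT	2010-02-22	2010-02-22	2010-03-07	14	14	487	1	5	5	5	0	0	5
98138	Male	FALSE	ANT	2010-02-22	2010-02-21	2010-04-03	42	42	1425	0	NA	NA	NA	NA	NA	NA
96403	Female	FALSE	ANT	2010-02-25	2010-02-26	2010-03-18	21	18	1821	0	NA	NA	NA	NA	NA	NA
96386	Female	FALSE	ANT	2010-03-01	2010-03-01	2010-05-31	92	92	4547	5	30	21	1	0	0	30
96390	Female	FALSE	ANT	2010-03-08	2010-03-08	2010-03-28	21	21	962	1	13	13	13	0	0	13
96398	Male	FALSE	ANT	2010-03-08	2010-03-08	2010-04-22	46	46	2643	5	25	7	3	0	0	25
96412	Female	FALSE	ANT	2010-03-08	2010-03-08	2010-03-22	15	15	860	2	9	5	4	0	0	9
98139	Male	FALSE	AU-SC	2010-10-13	2010-10-13	2010-11-22	41	41	2697	0	NA	NA	NA	NA	NA	NA
64235	Male	FALSE	AU-SC	2010-10-14	2010-10-14	2010-11-29	47	47	4335	1	3	3	3	0	0	3
98100	Female	FALSE	AU-SC	2010-10-14	2010-10-14	2010-12-01	49	49	3580	0	NA	NA	NA	NA	NA	NA
98114	Male	FALSE	AU-SC	2010-10-14	2010-10-31	2010-12-09	40	40	3225	0	NA	NA	NA	NA	NA	NA
98129	Female	TRUE	AU-SC	2010-10-15	2010-10-15	2011-01-29	107	104	6539	1	2	2	2	0	0	2
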