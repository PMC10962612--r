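taxon_id	ctrl01_d0030	ctrl01_d0060	ctrl01_d0090	ctrl01_d0120	ctrl01_d0150	ctrl01_d0180	ctrl02_d0030	ctrl02_d0060	ctrl02_d0090	ctrl02_d0120	ctrl02_d0150	ctrl02_d0180	sero01_d0030	sero01_d0060	sero01_d0090	sero01_d0120	sero01_d0150	sero01_d0180
taxon001	1919	1667	716	790	1327	1183	1218	2308	710	1379	552	1589	1186	524	343	2128	3015	4122
taxon002	27	23	5	10	17	20	20	64	9	13	11	29	12	19	9	26	69	48
taxon003	79	89	8	26	31	40	46	106	54	19	6	43	20	31	5	65	79	84
taxon004	76	129	30	14	34	67	44	76	40	17	16	67	18	73	2	74	123	119
taxon005	16	77	14	12	15	24	34	37	15	21	17	27	5	9	11	32	60	30
taxon006	12	32	22	36	29	51	51	23	14	20	11	35	20	11	3	24	95	26
taxon007	121	333	223	147	216	317	195	259	214	175	96	215	119	251	42	383	586	155
taxon008	50	85	89	70	53	92	112	80	100	55	22	69	57	48	10	50	107	72
taxon009	113	55	100	84	130	169	96	61	157	185	96	51	59	48	77	39	36	7
taxon010	1268	550	962	1341	637	1579	924	459	1858	892	2849	883	700	1433	1197	436	309	71
taxon011	154	92	119	109	115	70	167	27	256	103	111	154	60	137	110	35	45	23
taxon012	1165	1868	2712	2361	2396	1388	2093	1500	1573	2121	1213	1838	2744	2416	3191	1708	476	243
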