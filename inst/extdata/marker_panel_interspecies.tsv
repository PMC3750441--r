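region_id	origin	size	pct_difference_interspecies	pct_difference_intraspecies	euclid_to_reference	sd
rps14_mt	mt	297	37.71	0.34	0.397	0.046
ycf34	pt	252-261	33.72	0.00	0.409	0.038
rps14_mt-atp9	mt	102-195	32.83	0.00	0.500	0.048
rps4_mt	mt	726	32.09	0.41	0.260	0.031
rpl6_mt	mt	552	32.07	0.36	0.263	0.036
ycf34-psbD	pt	204-224	31.72	0.13	0.211	0.018
rpl5_mt	mt	525-540	31.67	0.57	0.299	0.037
clpA	pt	447-450	29.33	0.22	0.328	0.040
orf53	mt	156-162	29.01	0.00	0.258	0.041
rpl14_mt	mt	381	28.35	0.79	0.167	0.023
trnQ(uug)-groEL	pt	269-274	28.00	0.00	0.253	0.032
trnL(uag)-trnW(cca)	pt	648-673	27.99	0.46	0.234	0.021
ITS2	nc	385-499	27.67	0.52	NA	NA
rps2-rpoC2	pt	162-193	25.63	1.04	0.281	0.036
rpl16_mt	mt	432	24.54	0.00	0.098	0.018
nad4	mt	1578	23.76	0.63	0.038	0.008
atp9-rps13_mt	mt	215-233	23.50	0.43	0.107	0.022
ccs1	pt	1260-1272	22.90	0.00	0.111	0.010
rpl1	pt	687	22.56	0.00	0.114	0.012
ilvB	pt	1479	21.37	0.00	0.084	0.008
rpl6	pt	543	20.99	0.18	0.054	0.008
ccsA	pt	918-921	20.96	0.22	0.105	0.015
chlN	pt	1326-1335	20.37	0.00	0.062	0.008
ycf59	pt	1044	20.31	0.00	0.054	0.007
cbbX	pt	1011	19.88	0.10	0.053	0.008
chlL	pt	867	19.26	0.12	0.026	0.005
rps4	pt	627	19.14	0.00	0.029	0.005
rpoB	pt	3168	19.10	0.03	0.034	0.004
dnaK	pt	1809	19.02	0.11	0.030	0.004
clpC-II	pt	1155	18.87	0.09	0.020	0.004
atp8-orf228	mt	1294-1413	18.55	0.29	0.140	0.012
chlB	pt	1521-1524	18.37	0.00	0.023	0.005
ThiS-rbcL	pt	314-330	18.15	0.00	0.052	0.011
nad3	mt	369	17.89	0.27	0.108	0.009
ycf36-petN	pt	391-397	17.84	0.00	0.055	0.010
rps16	pt	255	17.65	0.00	0.119	0.025
cox1	mt	1521	17.55	0.13	0.144	0.018
ycf49	pt	294-297	16.84	0.00	0.035	0.007
ycf3	pt	504	16.47	0.00	0.059	0.009
rpl23	pt	360	16.11	0.00	0.062	0.007
cob	mt	1161	15.25	0.00	0.207	0.024
ilvB-rpl35	pt	504-512	15.04	0.00	0.091	0.019
nad2	mt	1482	14.71	0.34	0.039	0.005
hyp.protein	pt	645-699	14.57	0.14	0.086	0.009
rps13	pt	372	14.25	0.00	0.107	0.011
cox3	mt	813	13.65	0.12	0.221	0.021
cox2	mt	909	13.53	0.00	0.215	0.018
tufA	pt	1230-1275	13.36	0.08	0.067	0.009
rps7	pt	456-477	12.55	0.00	0.160	0.017
atpG	pt	477-483	11.18	0.00	0.171	0.014
rbcL	pt	1464	10.04	0.00	0.213	0.021
psaE	pt	204	9.80	0.00	0.199	0.017
rrn23_mt	mt	2235	8.18	0.18	0.365	0.038
rrn16_mt	mt	1491-1494	6.87	0.00	0.381	0.035
psbA	pt	1083	4.16	0.00	0.364	0.036
18S	nc	1790-1792	2.51	0.16	NA	NA
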