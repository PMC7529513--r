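qtl_id	chrom	breed	trait	pos	maf	neglog10p	effect
2	3	HOL	PC	15540709	0.03	23.3	-0.461
6	5	HOL	PY	89037941	0.05	8.3	-0.273
8	5	HOL	FC	93944234	0.44	26.4	0.242
8	5	HOL	FY	93954751	0.214	12.3	0.1883
12	5	HOL	PC	118283121	0.2	11.3	-0.167
13	6	HOL	FC	37742024	0.01	9.7	-0.442
13	6	HOL	PC	37742024	0.012	24.3	-0.701
14	6	HOL	PC	87001138	0.11	24.1	0.448
14	6	HOL	PY	87174212	0.31	39.6	-0.156
19	11	HOL	FC	103294772	0.48	10.2	0.13
22	14	HOL	FC	1881400	0.229	95.1	0.916
22	14	HOL	MY	1801116	0.203	100.8	-0.49
22	14	HOL	FY	1801116	0.203	128.2	0.5803
22	14	HOL	PY	1801116	0.203	22.3	-0.231
22	14	HOL	PC	1801116	0.203	121.1	0.5048
24	14	HOL	FC	66419482	0.11	13.3	-0.257
24	14	HOL	MY	66326942	0.147	13.4	0.2125
24	14	HOL	PC	66326942	0.147	35.7	-0.334
25	15	HOL	PC	28802897	0.21	8.4	0.153
27	19	HOL	FC	51321632	0.32	14.0	0.174
27	19	HOL	FY	51323848	0.318	10.9	0.1618
28	20	HOL	FY	7661288	0.02	8.6	0.341
28	20	HOL	PY	7339763	0.001	8.3	1.0799
29	20	HOL	PC	30031902	0.22	11.7	-0.199
30	20	HOL	PC	32254539	0.22	9.6	-0.357
30	20	HOL	MY	32265342	0.197	8.2	0.1864
30	20	HOL	FC	32296239	0.201	17.4	-0.274
33	27	HOL	FC	36221754	0.38	11.1	-0.149
35	29	HOL	PC	9563396	0.31	12.6	0.158
36.2	9	HOL	PC	42393898	0.15	11.6	-0.226
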