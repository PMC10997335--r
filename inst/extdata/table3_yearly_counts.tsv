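year	fluconazole	voriconazole	posaconazole	itraconazole	isavuconazole
2004	24	26	0	28	0
2005	23	21	0	19	0
2006	31	19	1	14	0
2007	22	11	7	20	0
2008	42	4	4	34	0
2009	17	16	5	31	0
2010	20	32	1	24	0
2011	31	31	6	24	0
2012	34	38	6	30	0
2013	31	22	0	17	0
2014	24	20	2	15	0
2015	45	29	5	12	1
2016	61	28	6	11	1
2017	57	30	11	20	3
2018	56	30	14	37	1
2019	49	41	6	24	2
2020	31	30	6	68	1
2021	28	26	10	21	2
2022	33	37	5	11	3
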