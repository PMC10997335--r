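drug	pt	n	ror	ror_low	ror_high	prr	prr_low	prr_high
fluconazole	Long qt syndrome	31	51.58	36.06	73.78	51.30	35.93	73.24
fluconazole	Torsade de pointes	87	40.57	32.75	50.25	39.96	32.36	49.34
fluconazole	Transposition of the great vessels	11	37.94	20.87	68.98	37.87	20.85	68.77
fluconazole	Kounis syndrome	10	21.14	11.33	39.46	21.11	11.32	39.35
fluconazole	Fallot's tetralogy	6	15.49	6.93	34.62	15.48	6.93	34.55
fluconazole	Ventricular tachycardia	38	9.29	6.75	12.79	9.24	6.72	12.69
fluconazole	Ventricular arrhythmia	8	8.17	4.08	16.36	8.16	4.07	16.33
fluconazole	Ventricular fibrillation	21	7.46	4.86	11.46	7.44	4.85	11.41
fluconazole	Atrioventricular block first degree	5	4.15	1.73	9.99	4.15	1.73	9.97
fluconazole	Ventricular extrasystoles	9	3.59	1.86	6.90	3.58	1.86	6.89
fluconazole	Sinus bradycardia	8	3.34	1.67	6.69	3.59	1.09	10.52
fluconazole	Pericarditis	7	3.10	1.48	6.52	3.34	1.67	6.68
fluconazole	Cardiac failure chronic	3	3.39	1.09	10.53	3.10	1.48	6.50
voriconazole	Fungal endocarditis	9	129.64	65.55	256.39	129.47	65.52	255.85
voriconazole	Torsade de pointes	21	7.75	5.04	11.91	7.73	5.04	11.86
voriconazole	Sinus arrest	3	6.45	2.07	20.05	6.45	2.07	20.03
voriconazole	Haemoptysis	41	5.36	3.94	7.30	5.34	3.93	7.25
voriconazole	Ventricular hypokinesia	4	4.30	1.61	11.47	4.30	1.61	11.46
voriconazole	Cardiotoxicity	8	3.11	1.55	6.23	3.11	1.55	6.22
voriconazole	Cardiac failure acute	5	3.10	1.29	7.46	3.10	1.29	7.45
voriconazole	Ventricular tachycardia	12	2.37	1.35	4.18	2.37	1.35	4.17
voriconazole	Supraventricular tachycardia	7	2.45	1.17	5.14	2.45	1.17	5.14
voriconazole	Pericardial effusion	14	2.23	1.32	3.76	2.22	1.32	3.76
voriconazole	Ventricular extrasystoles	7	2.27	1.08	4.77	2.27	1.08	4.76
itraconazole	Reperfusion arrhythmia	3	417.37	126.54	1376.60	416.90	126.55	1373.45
itraconazole	Cardiotoxicity	49	50.09	37.69	66.56	49.20	37.21	65.05
itraconazole	Acute left ventricular failure	4	49.93	18.61	134.01	49.86	18.61	133.63
itraconazole	Left ventricular failure	6	16.61	7.44	37.08	16.58	7.44	36.93
itraconazole	Atrioventricular block	14	14.82	8.76	25.09	14.75	8.74	24.90
itraconazole	Left ventricular dysfunction	9	13.27	6.89	25.57	13.23	6.88	25.43
itraconazole	Torsade de pointes	13	12.27	7.11	21.17	12.21	7.09	21.02
itraconazole	Supraventricular extrasystoles	4	10.87	4.07	29.02	10.85	4.07	28.94
itraconazole	Cardiac failure acute	6	9.53	4.27	21.25	9.51	4.27	21.17
itraconazole	Ventricular extrasystoles	9	7.49	3.89	14.41	7.46	3.89	14.34
itraconazole	Myocarditis	7	6.81	3.24	14.31	6.80	3.24	14.25
itraconazole	Cardiac failure	55	6.12	4.68	7.99	6.01	4.63	7.81
itraconazole	Cardiomegaly	9	6.11	3.18	11.77	6.10	3.17	11.71
itraconazole	Haemoptysis	18	6.01	3.78	9.56	5.98	3.77	9.48
itraconazole	Pericardial effusion	14	5.71	3.38	9.66	5.69	3.37	9.60
itraconazole	Sinus bradycardia	6	2.29	2.34	11.65	5.21	2.34	11.60
itraconazole	Pulmonary oedema	22	4.53	2.97	6.89	4.50	2.97	6.82
itraconazole	Atrioventricular block complete	4	5.08	1.91	13.56	5.08	1.91	13.53
itraconazole	Arrhythmia	27	4.43	3.03	6.48	4.40	3.02	6.40
itraconazole	Oedema peripheral	59	3.95	3.05	5.11	3.88	3.02	5.00
itraconazole	Atrial flutter	4	4.50	1.69	12.00	4.49	1.69	11.97
itraconazole	Arteriosclerosis coronary artery	3	3.82	1.23	11.86	3.82	1.23	11.83
itraconazole	Right ventricular failure	3	3.58	1.15	11.10	3.57	1.15	11.08
itraconazole	Cardiac failure congestive	26	2.21	1.50	3.25	2.20	1.50	3.22
itraconazole	Bradycardia	15	2.29	1.38	3.81	2.29	1.38	3.79
itraconazole	Chest discomfort	23	2.18	1.45	3.28	2.17	1.44	3.26
posaconazole	Ventricular arrhythmia	3	11.22	3.61	34.82	11.19	3.61	34.68
posaconazole	Torsade de pointes	4	6.61	2.48	17.65	6.60	2.48	17.57
posaconazole	Ventricular tachycardia	6	5.34	2.40	11.92	5.33	2.40	11.84
posaconazole	Cardiac arrest	14	2.44	1.44	4.14	2.43	1.44	4.09
posaconazole	Bradycardia	8	2.15	1.07	4.31	2.15	1.08	4.28
isavuconazole	Haemoptysis	3	6.76	2.17	21.05	6.72	2.18	20.74
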