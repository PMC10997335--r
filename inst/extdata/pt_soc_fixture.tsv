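pt	soc
Long qt syndrome	Cardiac disorders
Torsade de pointes	Cardiac disorders
Transposition of the great vessels	Cardiac disorders
Kounis syndrome	Cardiac disorders
Fallot's tetralogy	Cardiac disorders
Ventricular tachycardia	Cardiac disorders
Ventricular arrhythmia	Cardiac disorders
Ventricular fibrillation	Cardiac disorders
Atrioventricular block first degree	Cardiac disorders
Ventricular extrasystoles	Cardiac disorders
Sinus bradycardia	Cardiac disorders
Pericarditis	Cardiac disorders
Cardiac failure chronic	Cardiac disorders
Fungal endocarditis	Cardiac disorders
Sinus arrest	Cardiac disorders
Haemoptysis	Cardiac disorders
Ventricular hypokinesia	Cardiac disorders
Cardiotoxicity	Cardiac disorders
Cardiac failure acute	Cardiac disorders
Supraventricular tachycardia	Cardiac disorders
Pericardial effusion	Cardiac disorders
Reperfusion arrhythmia	Cardiac disorders
Acute left ventricular failure	Cardiac disorders
Left ventricular failure	Cardiac disorders
Atrioventricular block	Cardiac disorders
Left ventricular dysfunction	Cardiac disorders
Supraventricular extrasystoles	Cardiac disorders
Myocarditis	Cardiac disorders
Cardiac failure	Cardiac disorders
Cardiomegaly	Cardiac disorders
Pulmonary oedema	Cardiac disorders
Atrioventricular block complete	Cardiac disorders
Arrhythmia	Cardiac disorders
Oedema peripheral	Cardiac disorders
Atrial flutter	Cardiac disorders
Arteriosclerosis coronary artery	Cardiac disorders
Right ventricular failure	Cardiac disorders
Cardiac failure congestive	Cardiac disorders
Bradycardia	Cardiac disorders
Chest discomfort	Cardiac disorders
Cardiac arrest	Cardiac disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Alopecia	Skin and subcutaneous tissue disorders
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Abdominal pain	Gastrointestinal disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Tremor	Nervous system disorders
Pyrexia	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Drug ineffective	General disorders and administration site conditions
Hepatotoxicity	Hepatobiliary disorders
Hepatic function abnormal	Hepatobiliary disorders
Renal impairment	Renal and urinary disorders
Acute kidney injury	Renal and urinary disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Cough	Respiratory, thoracic and mediastinal disorders
Anaemia	Blood and lymphatic system disorders
Thrombocytopenia	Blood and lymphatic system disorders
Insomnia	Psychiatric disorders
Hallucination	Psychiatric disorders
Visual impairment	Eye disorders
Blood creatinine increased	Investigations
Electrocardiogram qt prolonged	Investigations
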