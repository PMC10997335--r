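drug	outcome	n
fluconazole	hospitalization	160
fluconazole	death	77
fluconazole	life_threatening	140
fluconazole	disability	15
fluconazole	congenital_anomaly	15
fluconazole	other	252
voriconazole	hospitalization	93
voriconazole	death	128
voriconazole	life_threatening	54
voriconazole	disability	2
voriconazole	congenital_anomaly	0
voriconazole	other	214
posaconazole	hospitalization	31
posaconazole	death	23
posaconazole	life_threatening	10
posaconazole	disability	1
posaconazole	congenital_anomaly	0
posaconazole	other	30
itraconazole	hospitalization	107
itraconazole	death	48
itraconazole	life_threatening	36
itraconazole	disability	4
itraconazole	congenital_anomaly	0
itraconazole	other	265
isavuconazole	hospitalization	1
isavuconazole	death	1
isavuconazole	life_threatening	0
isavuconazole	disability	0
isavuconazole	congenital_anomaly	0
isavuconazole	other	12
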