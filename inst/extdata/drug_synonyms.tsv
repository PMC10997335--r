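raw_name	canonical
fluconazole	fluconazole
diflucan	fluconazole
fluconazol	fluconazole
fluconazolum	fluconazole
voriconazole	voriconazole
vfend	voriconazole
voriconazol	voriconazole
itraconazole	itraconazole
sporanox	itraconazole
onmel	itraconazole
tolsura	itraconazole
itraconazol	itraconazole
posaconazole	posaconazole
noxafil	posaconazole
posaconazol	posaconazole
isavuconazole	isavuconazole
isavuconazonium	isavuconazole
isavuconazonium sulfate	isavuconazole
cresemba	isavuconazole
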