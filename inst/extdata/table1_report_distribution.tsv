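drug	taa_ae_n	cardiac_ae_n	ps_n
fluconazole	18954	2633	659
voriconazole	21391	1981	491
itraconazole	6982	1203	460
posaconazole	3943	333	95
isavuconazole	2594	24	14
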