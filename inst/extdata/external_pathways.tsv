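pathway	step	name	smiles
reticuline-to-laudanine	0	reticuline	COc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O
reticuline-to-laudanine	1	Laudanine	COc1ccc(CC2N(C)CCc3cc(OC)c(OC)cc23)cc1O
scoulerine-to-cheilanthifoline	0	scoulerine	COc1ccc2c(c1O)CN1CCc3cc(OC)c(O)cc3C1C2
scoulerine-to-cheilanthifoline	1	Cheilanthifoline	COc1cc2CCN3C(c2cc1O)Cc1c(C3)c2OCOc2cc1
canadine-to-berberine	0	canadine	COc1ccc2c(c1OC)CN1CCc3cc4OCOc4cc3C1C2
canadine-to-berberine	1	Berberine	COc1ccc2cc3[n+](cc2c1OC)CCc1cc2c(cc1-3)OCO2
thc-to-palmatine	0	tetrahydrocolumbamine	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(O)cc3C1C2
thc-to-palmatine	1	Tetrahydropalmatine	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(OC)cc3C1C2
thc-to-palmatine	2	Palmatine	COc1ccc2cc3[n+](cc2c1OC)CCc1cc(OC)c(OC)cc1-3
reticuline-to-dehydroreticuline	0	reticuline	COc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O
reticuline-to-dehydroreticuline	1	1,2-Dehydroreticuline	COc1ccc(CC2=[N+](C)CCc3cc(OC)c(O)cc23)cc1O
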