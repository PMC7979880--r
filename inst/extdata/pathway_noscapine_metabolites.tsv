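order	name	smiles
1	norcoclaurine	Oc1ccc(CC2NCCc3cc(O)c(O)cc23)cc1
2	coclaurine	Oc1ccc(CC2NCCc3cc(OC)c(O)cc23)cc1
3	N-methylcoclaurine	Oc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1
4	3'-hydroxy-N-methylcoclaurine	Oc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O
5	reticuline	COc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O
6	scoulerine	COc1ccc2c(c1O)CN1CCc3cc(OC)c(O)cc3C1C2
7	tetrahydrocolumbamine	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(O)cc3C1C2
8	canadine	COc1ccc2c(c1OC)CN1CCc3cc4OCOc4cc3C1C2
9	N-methylcanadine	COc1ccc2c(c1OC)C[N+]1(C)CCc3cc4OCOc4cc3C1C2
10	1-hydroxy-N-methylcanadine	COc1ccc2c(c1OC)C[N+]1(C)CCc3cc4OCOc4c(O)c3C1C2
11	1,13-dihydroxy-N-methylcanadine	COc1ccc2c(c1OC)C[N+]1(C)CCc3cc4OCOc4c(O)c3C1C2O
12	1-hydroxy-13-O-acetyl-N-methylcanadine	COc1ccc2c(c1OC)C[N+]1(C)CCc3cc4OCOc4c(O)c3C1C2OC(C)=O
13	4'-O-desmethyl-3-O-acetylpapaveroxine	COc1ccc(C(OC(C)=O)C2c3c(O)c4OCOc4cc3CCN2C)c(C=O)c1OC
14	3-O-acetylpapaveroxine	COc1ccc(C(OC(C)=O)C2c3c(OC)c4OCOc4cc3CCN2C)c(C=O)c1OC
15	narcotolinehemiacetal	COc1ccc(C(O)C2c3c(O)c4OCOc4cc3CCN2C)c(C=O)c1OC
16	narcotinehemiacetal	COc1ccc(C(O)C2c3c(OC)c4OCOc4cc3CCN2C)c(C=O)c1OC
17	noscapine	COc1ccc2c(c1OC)C(=O)OC2C4c2c(OC)c3OCOc3cc2CCN4C
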