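name	smiles	database	identifier
norcoclaurine	Oc1ccc(CC2NCCc3cc(O)c(O)cc23)cc1	KEGG	BIO-0001
coclaurine	Oc1ccc(CC2NCCc3cc(OC)c(O)cc23)cc1	KEGG	BIO-0002
N-methylcoclaurine	Oc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1	KEGG	BIO-0003
3'-hydroxy-N-methylcoclaurine	Oc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O	KEGG	BIO-0004
reticuline	COc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O	KEGG	BIO-0005
scoulerine	COc1ccc2c(c1O)CN1CCc3cc(OC)c(O)cc3C1C2	KEGG	BIO-0006
tetrahydrocolumbamine	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(O)cc3C1C2	KEGG	BIO-0007
canadine	COc1ccc2c(c1OC)CN1CCc3cc4OCOc4cc3C1C2	KEGG	BIO-0008
N-methylcanadine	COc1ccc2c(c1OC)C[N+]1(C)CCc3cc4OCOc4cc3C1C2	MetaCyc	BIO-0009
1-hydroxy-N-methylcanadine	COc1ccc2c(c1OC)C[N+]1(C)CCc3cc4OCOc4c(O)c3C1C2	MetaCyc	BIO-0010
1,13-dihydroxy-N-methylcanadine	COc1ccc2c(c1OC)C[N+]1(C)CCc3cc4OCOc4c(O)c3C1C2O	MetaCyc	BIO-0011
1-hydroxy-13-O-acetyl-N-methylcanadine	COc1ccc2c(c1OC)C[N+]1(C)CCc3cc4OCOc4c(O)c3C1C2OC(C)=O	MetaCyc	BIO-0012
4'-O-desmethyl-3-O-acetylpapaveroxine	COc1ccc(C(OC(C)=O)C2c3c(O)c4OCOc4cc3CCN2C)c(C=O)c1OC	MetaCyc	BIO-0013
3-O-acetylpapaveroxine	COc1ccc(C(OC(C)=O)C2c3c(OC)c4OCOc4cc3CCN2C)c(C=O)c1OC	MetaCyc	BIO-0014
narcotolinehemiacetal	COc1ccc(C(O)C2c3c(O)c4OCOc4cc3CCN2C)c(C=O)c1OC	MetaCyc	BIO-0015
narcotinehemiacetal	COc1ccc(C(O)C2c3c(OC)c4OCOc4cc3CCN2C)c(C=O)c1OC	MetaCyc	BIO-0016
noscapine	COc1ccc2c(c1OC)C(=O)OC2C4c2c(OC)c3OCOc3cc2CCN4C	KEGG	BIO-0017
Tetrahydropalmatine	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(OC)cc3C1C2	KEGG	BIO-0018
Armepavine	Oc1ccc(CC2N(C)CCc3cc(OC)c(OC)cc23)cc1	KEGG	BIO-0019
Laudanine	COc1ccc(CC2N(C)CCc3cc(OC)c(OC)cc23)cc1O	KEGG	BIO-0020
Nandinine	COc1ccc2c(c1O)CN1CCc3cc4OCOc4cc3C1C2	KNApSAcK	BIO-0021
Berberine	COc1ccc2cc3[n+](cc2c1OC)CCc1cc2c(cc1-3)OCO2	KEGG	BIO-0022
Columbamine	COc1ccc2cc3[n+](cc2c1OC)CCc1cc(OC)c(O)cc1-3	KEGG	BIO-0023
Palmatine	COc1ccc2cc3[n+](cc2c1OC)CCc1cc(OC)c(OC)cc1-3	KEGG	BIO-0024
Norreticuline	COc1ccc(CC2NCCc3cc(OC)c(O)cc23)cc1O	KNApSAcK	BIO-0025
Codamine	COc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1OC	KNApSAcK	BIO-0026
Cheilanthifoline	COc1cc2CCN3C(c2cc1O)Cc1c(C3)c2OCOc2cc1	MetaCyc	BIO-0027
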