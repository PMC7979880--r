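name	smiles	database	identifier
O-methylarmepavine	COc1ccc(CC2N(C)CCc3cc(OC)c(OC)cc23)cc1	PubChem	CHM-0001
7-O-methylnorcoclaurine	Oc1ccc(CC2NCCc3cc(O)c(OC)cc23)cc1	PubChem	CHM-0002
Tetrahydropalmatrubine	COc1ccc2c(c1O)CN1CCc3cc(OC)c(OC)cc3C1C2	PubChem	CHM-0003
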