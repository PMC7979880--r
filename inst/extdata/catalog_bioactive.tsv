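name	smiles	database	identifier
Norlaudanosoline	Oc1ccc(CC2NCCc3cc(O)c(O)cc23)cc1O	ChEBI	ACT-0001
Tetrahydropalmatine	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(OC)cc3C1C2	ChEMBL	ACT-0002
Papaverine	COc1ccc(Cc2nccc3cc(OC)c(OC)cc23)cc1OC	ChEBI	ACT-0003
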