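reaction_id	ec	native_substrate	substrate_type	organism	has_sequence	rule_id	substrate_smiles	product_smiles
R001	2.1.1.291	(S)-reticuline	BIA	Papaver somniferum	TRUE	omt_aromatic	COc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O	COc1ccc(CC2N(C)CCc3cc(OC)c(OC)cc23)cc1O
R002	2.1.1.118	Columbamine	BIA	Coptis japonica	TRUE	omt_aromatic	COc1ccc2cc3[n+](cc2c1OC)CCc1cc(OC)c(O)cc1-3	COc1ccc2cc3[n+](cc2c1OC)CCc1cc(OC)c(OC)cc1-3
R003	2.1.1.128	(S)-norcoclaurine	BIA	Papaver somniferum	TRUE	omt_aromatic	Oc1ccc(CC2NCCc3cc(O)c(O)cc23)cc1	Oc1ccc(CC2NCCc3cc(OC)c(O)cc23)cc1
R004	2.1.1.116	3'-hydroxy-N-methyl-(S)-coclaurine	BIA	Papaver somniferum	TRUE	omt_aromatic	Oc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O	COc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O
R005	2.1.1.117	(S)-scoulerine	BIA	Papaver somniferum	TRUE	omt_aromatic	COc1ccc2c(c1O)CN1CCc3cc(OC)c(O)cc3C1C2	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(O)cc3C1C2
R006	2.1.1.146	Isoeugenol	Phenylpropanoid	Ocimum basilicum	TRUE	omt_aromatic	CC=Cc1ccc(O)c(OC)c1	CC=Cc1ccc(OC)c(OC)c1
R007	2.1.1.38	O-demethylpuromycin (synthetic surrogate)	Antibiotic	Streptomyces alboniger	TRUE	omt_aromatic	COC(=O)C(N)Cc1ccc(O)cc1	COC(=O)C(N)Cc1ccc(OC)cc1
R008	2.1.1.6	Catechol	Phenol	Homo sapiens	TRUE	omt_aromatic	Oc1ccccc1O	COc1ccccc1O
R009	2.1.1.212	2,4',7-trihydroxyisoflavanone (synthetic surrogate)	Flavonoid	Lotus japonicus	TRUE	omt_aromatic	O=C1c2ccc(O)cc2OCC1c1ccc(O)cc1	O=C1c2ccc(O)cc2OCC1c1ccc(OC)cc1
R010	2.1.1.4	N-acetylserotonin	Neurotransmitter	Homo sapiens	TRUE	omt_aromatic	CC(=O)NCCc1c[nH]c2ccc(O)cc12	CC(=O)NCCc1c[nH]c2ccc(OC)cc12
R011	2.1.1.231	4'-hydroxyflavone	Flavonoid	Glycine max	TRUE	omt_aromatic	O=C1C=C(c2ccc(O)cc2)Oc2ccccc21	O=C1C=C(c2ccc(OC)cc2)Oc2ccccc21
R012	2.1.1.68	(E)-caffeate	Phenylpropanoid	Arabidopsis thaliana	TRUE	omt_aromatic	OC(=O)C=Cc1ccc(O)c(O)c1	OC(=O)C=Cc1ccc(O)c(OC)c1
R013	2.1.1.104	Caffeoyl-CoA (synthetic surrogate ester)	Phenylpropanoid	Arabidopsis thaliana	TRUE	omt_aromatic	COC(=O)C=Cc1ccc(O)c(O)c1	COC(=O)C=Cc1ccc(O)c(OC)c1
R014	2.1.1.150	(E)-caffeate	Phenylpropanoid	Medicago sativa	TRUE	omt_aromatic	OC(=O)C=Cc1ccc(O)c(O)c1	OC(=O)C=Cc1ccc(OC)c(O)c1
R015	2.1.1.222	3-demethylubiquinol (synthetic surrogate)	Quinone	Escherichia coli	TRUE	omt_aromatic	Cc1cc(O)c(O)c(OC)c1	Cc1cc(O)c(OC)c(OC)c1
R016	2.1.1.279	trans-Anol	Phenol	Pimpinella anisum	TRUE	omt_aromatic	CC=Cc1ccc(O)cc1	CC=Cc1ccc(OC)cc1
R017	2.1.1.94	16-hydroxytabersonine (synthetic surrogate)	Terpene indole alkaloid	Catharanthus roseus	TRUE	omt_aromatic	CN1CCc2cc(O)ccc21	CN1CCc2cc(OC)ccc21
R018	2.1.1.114	3,4-dihydroxy-5-prenylbenzoate (synthetic surrogate)	Quinone	Saccharomyces cerevisiae	TRUE	omt_aromatic	OC(=O)c1cc(O)c(O)c(CC=C(C)C)c1	OC(=O)c1cc(OC)c(O)c(CC=C(C)C)c1
R019	2.1.1.140	(S)-coclaurine	BIA	Papaver somniferum	TRUE	nmt_secondary	Oc1ccc(CC2NCCc3cc(OC)c(O)cc23)cc1	Oc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1
R020	1.14.19.74	(S)-tetrahydrocolumbamine	BIA	Coptis japonica	TRUE	methylenedioxy_bridge	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(O)cc3C1C2	COc1ccc2c(c1OC)CN1CCc3cc4OCOc4cc3C1C2
R021	1.14.19.73	(S)-scoulerine	BIA	Eschscholzia californica	TRUE	methylenedioxy_bridge	COc1ccc2c(c1O)CN1CCc3cc(OC)c(O)cc3C1C2	COc1ccc2c(c1O)CN1CCc3cc4OCOc4cc3C1C2
R022	2.1.1.-	(S)-tetrahydrocolumbamine	BIA	orphan (no sequence)	FALSE	omt_aromatic	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(O)cc3C1C2	COc1ccc2c(c1OC)CN1CCc3cc(OC)c(OC)cc3C1C2
R023	1.3.3.8	(S)-canadine	BIA	Berberis wilsoniae	TRUE	thb_oxidase	COc1ccc2c(c1OC)CN1CCc3cc4OCOc4cc3C1C2	COc1ccc2cc3[n+](cc2c1OC)CCc1cc2c(cc1-3)OCO2
R024	1.21.3.3	(S)-reticuline	BIA	Eschscholzia californica	TRUE	berberine_bridge	COc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O	COc1ccc2c(c1O)CN1CCc3cc(OC)c(O)cc3C1C2
R025	1.14.14.102	(S)-N-methylcoclaurine	BIA	Papaver somniferum	TRUE	hydroxylation_aromatic	Oc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1	Oc1ccc(CC2N(C)CCc3cc(OC)c(O)cc23)cc1O
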