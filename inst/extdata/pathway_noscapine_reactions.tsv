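step	substrate	product	rule_id	enzyme
1	norcoclaurine	coclaurine	omt_aromatic	6OMT
2	coclaurine	N-methylcoclaurine	nmt_secondary	CNMT
3	N-methylcoclaurine	3'-hydroxy-N-methylcoclaurine	hydroxylation_aromatic	NMCH (CYP80B)
4	3'-hydroxy-N-methylcoclaurine	reticuline	omt_aromatic	4'OMT
5	reticuline	scoulerine	berberine_bridge	BBE
6	scoulerine	tetrahydrocolumbamine	omt_aromatic	S9OMT
7	tetrahydrocolumbamine	canadine	methylenedioxy_bridge	CAS (CYP719A)
8	canadine	N-methylcanadine	nmt_tertiary	TNMT
9	N-methylcanadine	1-hydroxy-N-methylcanadine	hydroxylation_aromatic	CYP82Y1
10	1-hydroxy-N-methylcanadine	1,13-dihydroxy-N-methylcanadine	hydroxylation_benzylic	CYP82X2
11	1,13-dihydroxy-N-methylcanadine	1-hydroxy-13-O-acetyl-N-methylcanadine	o_acetylation	AT1
12	1-hydroxy-13-O-acetyl-N-methylcanadine	4'-O-desmethyl-3-O-acetylpapaveroxine	cn_cleavage_oxidative	CYP82X1
13	4'-O-desmethyl-3-O-acetylpapaveroxine	3-O-acetylpapaveroxine	omt_aromatic	MT2
14	4'-O-desmethyl-3-O-acetylpapaveroxine	narcotolinehemiacetal	ester_hydrolysis	CXE1
15	3-O-acetylpapaveroxine	narcotinehemiacetal	ester_hydrolysis	CXE1
16	narcotolinehemiacetal	narcotinehemiacetal	omt_aromatic	MT2
17	narcotinehemiacetal	noscapine	lactonization_oxidative	NOS
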