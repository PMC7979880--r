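name	citations	patents	total_printed
Berberine	5430	6751	12154
Tetrahydropalmatine	530	355	885
Columbamine	131	235	366
Salutaridine	85	264	349
Norlaudanosoline	144	177	321
Stepholidine	157	140	297
Allocryptopine	111	159	270
Laudanine	23	112	135
Codamine	13	61	74
Norreticuline	33	40	73
Corytuberine	18	39	57
Lambertine	30	23	53
Armepavine	28	15	43
1,2-Dehydroreticuline	3	40	43
Nandinine	1	39	40
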