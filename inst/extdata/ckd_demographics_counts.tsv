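variable	level	mild	moderate	severe
gender	female	18	10	4
gender	male	22	13	12
diabetes	no	36	14	10
diabetes	yes	4	9	6
hypercholesterolaemia	no	29	11	8
hypercholesterolaemia	yes	11	12	8
cvd	present	5	4	4
cvd	absent	35	19	12
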