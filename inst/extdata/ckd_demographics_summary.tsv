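variable	group	n	mean	sd
age	mild	40	52.2	17.1
age	moderate	23	59.3	16.4
age	severe	16	66.2	13.3
creatinine	mild	40	95.8	25.9
creatinine	moderate	23	152.3	26.0
creatinine	severe	16	222.4	68.3
gfr	mild	40	55.7	6.5
gfr	moderate	23	37.5	6.1
gfr	severe	16	26.5	9.8
weight	mild	40	79.4	17.3
weight	moderate	23	91.0	21.3
weight	severe	16	86.7	14.3
bmi	mild	40	28.6	6.0
bmi	moderate	23	31.6	6.7
bmi	severe	16	29.5	4.5
systolic_bp	mild	40	140.7	18.0
systolic_bp	moderate	23	144.5	19.1
systolic_bp	severe	16	146.6	17.9
diastolic_bp	mild	40	82.0	11.2
diastolic_bp	moderate	23	79.9	9.5
diastolic_bp	severe	16	80.5	9.8
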