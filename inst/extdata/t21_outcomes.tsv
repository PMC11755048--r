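case_index	status	age_years	gestational_age	z	ff_pct
1	true_positive	36	16	10.81	13.91
2	true_positive	38	17+4	13.40	14.43
3	true_positive	40	25+4	24.83	28.03
4	true_positive	47	14	10.46	16.07
5	true_positive	38	14+5	13.35	20.06
6	true_positive	46	21+3	7.85	11.34
7	true_positive	41	13+4	3.83	4.88
8	true_positive	36	15+4	9.77	12.55
9	true_positive	27	17+5	6.43	12.73
10	true_positive	29	12+3	11.64	16.20
11	true_positive	28	13+5	13.51	15.83
12	true_positive	41	13+6	6.79	12.22
13	true_positive	23	15+6	12.44	14.80
14	true_positive	40	18+4	9.90	14.38
1	false_positive	26	31	3.81	13.91
2	false_positive	30	18+1	3.04	24.9
1	false_negative	35	17+3	1.78	8.13
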