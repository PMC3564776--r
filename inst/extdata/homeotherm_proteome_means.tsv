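species	n_sequences	cvp_bias	tm_index	iupred	ivywrel	body_temp_c
HUMAN	50006	0.93	0.9	0.31	36.87	37
MOUSE	36368	0.97	0.93	0.29	37.16	37
TURTR	307	0.99	0.79	0.28	38.8	36.8
RAT	30926	1.02	0.97	0.28	37.17	37
BOVIN	23358	1.34	0.96	0.27	37.6	37
CHICK	19671	1.42	0.94	0.28	37.3	41
CANFA	24002	1.43	0.96	0.28	37.5	37
PIG	24692	1.61	0.98	0.28	37.43	37
MELGA	15899	1.72	0.94	0.27	37.66	41
TAEGU	16717	2.32	0.97	0.27	37.72	41
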