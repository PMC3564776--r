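protein	cvp_thermo	cvp_meso	tm_thermo_c	tm_meso_c
Rrp4	0.408	6.122	38	43.1
PolEta	5.71	3.67	49	43
Collagen	8.696	5.804	45-46	38-42
U2AF65	11.90	5.68	47	43
Nup170	-1.13	-4.86	57	36
Nup192	3.47	-3.33	57	36
Xylanase	-20.276	-22.523	60	50
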