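name	length_bp	tir_length_bp	ref_copy_number
Bari1	1728	26	7
Bari2	1064	253	5
HB	1653	29-31	60
hobo	2959	12	60
hopper	1435	33	26
mariner2	912	29	23
NOF	4347	308	8
P-element	2907	31	0
pogo	2121	26	50
S-element	1736	234	187
S2	1735	233	16
Tc1	1666	26	31
Tc3	1743	43	19
transib1	2167	43	3
transib2	2844	42	27
transib3	2883	45	13
transib4	2656	40	8
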