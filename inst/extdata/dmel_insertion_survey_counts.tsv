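element	specific	conserved	total_mapped	unannotated_conserved	ambiguous	unresolvable
Bari1	3	3	6	1	1	1
Bari2	0	4	4	2	0	0
HB	1	46	47	10	0	1
hobo	26	12	38	9	0	0
hopper	13	26	39	14	0	1
mariner2	1	34	35	16	0	0
NOF	1	2	3	1	0	0
P-element	16	0	16	0	0	0
pogo	18	4	22	0	1	2
S-element	12	74	86	39	2	10
S2	0	16	16	7	0	2
Tc1	1	43	44	15	0	3
Tc3	3	9	12	4	0	0
transib1	19	12	31	10	0	2
transib2	6	34	40	20	2	2
transib3	0	22	22	13	0	0
transib4	0	8	8	2	1	2
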