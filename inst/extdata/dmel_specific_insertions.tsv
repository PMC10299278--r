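element	contigs	insertion_coord	chromosome	target	heterochromatic
Bari1	892	3657194	X	AstA-R1	FALSE
Bari1	2963	20848451	3R	close to CG15696 and RpS30	FALSE
Bari1	3495	23430916	2L	-	TRUE
HB	2615	22744158	3L	CG7369NTs hotspot	TRUE
hobo	37	11731193	3R	CG12594	FALSE
hobo	142	8265913	3L	Dscam4	FALSE
hobo	153	13627239	3L	bru3	FALSE
hobo	166	31134735	3R	Gycβ100B	FALSE
hobo	364	11729899	X	inaF-A inaF-B inaF-C CG15221	FALSE
hobo	429	16058145	2L	beat-Ia	FALSE
hobo	1066	18846823	3R	Octα2R	FALSE
hobo	1121	11868933	2L	Pde1c	FALSE
hobo	2025,2026	8555248	X	IntS4	FALSE
hobo	2056	12963046	2L	-	FALSE
hobo	2063	13826443	3L	-	FALSE
hobo	2110	13678976	3L	bru3	FALSE
hobo	2111,2421,2422	14043231	2R	mam	FALSE
hobo	2124	8322604	3L	-	FALSE
hobo	2136	16515554	3L	CG43373	FALSE
hobo	2166	17551994	2L	-	FALSE
hobo	2167	19461109	2L	-	FALSE
hobo	2316	17384934	2R	lncRNA:CR44344	FALSE
hobo	2343	17184472	2R	lncRNA:CR44387	FALSE
hobo	2484	20235449	3R	Nlg4	FALSE
hobo	2673	5866909	2L	rau	FALSE
hobo		5649715	2L	DIP-θ	FALSE
hobo	2707	15577454	2R	-	FALSE
hobo	2762	9291978	3R	-	FALSE
hobo	2788	22850595	3R	lncRNA:CR43846	FALSE
hobo	3145	16137749	2L	lncRNA:CR44871	FALSE
hopper	165	18193772	X	Frq2	FALSE
hopper	526	16891891	2R	CG8910	FALSE
hopper	1264	22559246	X	1731{}3268NTs hotspot	TRUE
hopper	1938	5438793	3L	DIP-δ	FALSE
hopper	1989	20939569	2L	-	FALSE
hopper	2020	27859138	3R	CG34353	FALSE
hopper		27974479	3R	βTub97EF	FALSE
hopper	2615	22635736	3L	CG14459	FALSE
hopper	2675	21846566	3L	mub	FALSE
hopper	2725	2586216	2R	1360{}6340	TRUE
hopper	2760	12301235	3L	lncRNA:CR44550	FALSE
hopper	3122	24568086	3L	-	TRUE
hopper	3153	11661763	3L	CG32085	FALSE
mariner2	744	2671627	3R	Pzl	TRUE
NOF	2967	19470432	3R	Dys	FALSE
P-element	477	29765960	3R	close to kay	FALSE
P-element	491	21347168	3L	ebd2 CG32436	FALSE
P-element	869	10547695	X	spri	FALSE
P-element	1601	3250477	3L	lncRNA:CR43626	FALSE
P-element	1937	959438	3L	Glut1	FALSE
P-element	1938	1688826	3L	CG7991	FALSE
P-element	2081	7489940	2R	close to Coop	FALSE
P-element	2082	21697891	2L	noloNTs hotspot	FALSE
P-element	2111	14928221	2R	Kank	FALSE
P-element	2122	13477242	3L	close to CG10089	FALSE
P-element	2175	289069	2R	-	TRUE
P-element	2267	9698895	2L	Pka-C1	FALSE
P-element	2837	3059410	Y	-	TRUE
P-element	2907	3063077	2R	1360{}6347	TRUE
P-element	2967	19180631	3R	close to CG5555, CG14282, myd	FALSE
P-element	3114	11201707	X	gypsy5{}103	FALSE
pogo	166	30374902	3R	close to hdc	FALSE
pogo	222	15035178	3L	Sytβ	FALSE
pogo	235	21531991	2R	Egfr lncRNA:CR44725	FALSE
pogo	941	15069400	X	Lsd-2	FALSE
pogo	1021	15190453	2R	close to igl	FALSE
pogo	1202	21254529	X	Mnr	FALSE
pogo	1938	1684964	3L	CG7991	FALSE
pogo	1972	14688291	3R	Meltrin	FALSE
pogo	1993	22113023	2L	NTs hotspot	TRUE
pogo	2040	2801161	3R	Pzl	TRUE
pogo	2081	7839017	2R	Dgk	FALSE
pogo	2139	10889337	3L	close to OXA1L	FALSE
pogo	2166	17730485	2L	CadN	FALSE
pogo	2280	18913439	3R	close to Sgsh	FALSE
pogo	2410	20456532	2L	CG31687	FALSE
pogo	2615	22676271	3L	Jhbp6	FALSE
pogo	2768	17503189	3L	Oatp74D	FALSE
pogo	3136	24834544	3L	-	TRUE
S-element	67	9950745	2R	Mef2	FALSE
S-element	415	23313720	2L	-	TRUE
S-element	940	1664262	3R	Myo81F	TRUE
S-element	1611	23143313	3L	-	TRUE
S-element	2290	6076695	2L	-	FALSE
S-element	2353	3827600	3R	-	FALSE
S-element	2555	5674700	2R	Kune	TRUE
S-element	2660	4343666	2R	Gprk1	TRUE
S-element	2730	25200700	3L	CR40354	TRUE
S-element	3019	20099984	X	3S18{}177	FALSE
S-element	3138	5701549	2R	vlc	TRUE
S-element	3528	23400788	2L	-	TRUE
Tc1	2168	19339397	3L	close to CG32206	FALSE
Tc3	474	27356129	3L	Dbp80	TRUE
Tc3	578	3058866	3R	Pzl	TRUE
Tc3	3086	2884603	3R	Pzl	TRUE
transib1	67	9706842	2R	CG1773	FALSE
transib1	189	21115833	3L	ko	FALSE
transib1	410	15043410	2L	close to Su(H)	FALSE
transib1	718	26170465	3L	CR41320	TRUE
transib1	1760	2221072	2L	Ir40a	TRUE
transib1	1954,1955	282647	3L	RhoGEF3	FALSE
transib1	1973	14535266	3R	Pde6 lncRNA:CR46023	FALSE
transib1	1974,2041,2042	5533505	3L	close to CG13285	FALSE
transib1	2026	8675495	X	-	FALSE
transib1	2069	16135549	2R	spin	FALSE
transib1	2137	3473173	3L	CG42324	FALSE
transib1	2183	4285753	3R	cpx	FALSE
transib1	2302	11134998	3R	close to mAcon2	FALSE
transib1	2660	4322642	2R	Gprk1	TRUE
transib1	2877,2878	15028387	2L	CG33310 GABA-B-R1	FALSE
transib1	2932	23188307	2L	-	TRUE
transib1	3138	5787158	2R	-	TRUE
transib1	3782	22314057	3L	Ten-m	FALSE
transib1	3783	19656233	X	Elys	FALSE
transib2	2375	958213	2R	-	TRUE
transib2	2528,2530,2531	2831535	Y	-	TRUE
transib2	2789	14049394	3R	-	FALSE
transib2	3233	3146809	Y	-	TRUE
transib2	3311	3593807	Y	ORY	TRUE
transib2	3389	22662667	2L	CG40006	TRUE
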