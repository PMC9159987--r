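row	taxon_name	matches_type	hybrid_formula	knox3	ibr3	cp_haplotype	ploidy	mode	maternal_knox3	maternal_ibr3	sample_id	region	elevation
1	P. arisanensis	Y		F7F7F7	Y21Y87*	cxx	3	apo	F7	Y87	Chao2135	Taiwan	h
2	P. arisanensis	Y		F7F23	Y21Y87	cxx		apo	F7	Y87	Yang191030002	Taiwan	h
3	P. arisanensis			F4F5	Y21V22	cx	2	apo	F4 or F5	Y21	Chao2482	Taiwan	l
4	P. arisanensis			A5D4G1	S19T20*	cf'	3	apo			Chao2296	Taiwan	l
5	P. arisanensis		P. latipinna x P. arisanensis	D7F4F5	Y21V22W23	ca	3	apo	D7	W23	Hsu s.n.20130116	Taiwan	both
6	P. arisanensis			D5F3	W23Y24	ca	2	apo	D5	W23	Chao2483	China, Taiwan, Vietnam	l
7	P. arisanensis			D7F3G1	W5S14Y24	ca	3	apo	D7	W5	Chao2867	China	l
8	P. arisanensis			D7F3G1	S14V22W23	ca	3	apo	D7	W23	Chao2858	China	l
9	P. austrotaiwanensis			D3D5	W69W23	ct	2	apo	D3	W69	Hsu s.n.20130315	Taiwan	l
10	P. biaurita	Y			S25S25	ci			G1	S25	Kao 03,037	Costa Rica	l
11	P. biaurita			G1G1	S14S14	ci	2	apo	G1	S14	Chao2734	Cambodia, Thailand, China	l
12	P. biaurita			G1G4	S19S19	ci	2	apo	G1	S19	Chao2419	Malaysia	l
13	P. biaurita			G1G3	S19S19	ci		apo	G1	S19	Chao2752	China, Thailand	l
14	P. biaurita		P. biaurita x P. arisanensis	F7G1	S14S19Y21	ci		apo	G1	S14 or S19	Chao1317	China	h
15	P. biaurita		P. biaurita x P. arisanensis	F7G1*	S14Y21S25	ci	3	apo	G1	S14 or S25	Chao2484	Taiwan	both
16	P. biaurita		P. biaurita x P. arisanensis	F7G1*	Y21S70*	ci	3	apo	G1	S70	Chao2471	Taiwan	both
17	P. biaurita		P. arisanensis x P. biaurita	F16G1	S14Y87	cxx	2	apo	F16	Y87	Chao2478	Taiwan	both
18	P. biaurita		P. arisanensis x P. biaurita	F16G1	S14Y87	cxx		apo	G1	S14	Yang191029002	Taiwan	h
19	P. biaurita		P. latipinna x P. biaurita	D7G1	S25W23	ca'	2	apo	D7	W23	Chao2869	China	l
20	P. boninensis	Y		A7A7	T1T1	cb	2	sex	A7	T1	Chao1942	Japan	l
21	P. boninensis		P. boninensis x unknown	A1A7D5	W2T1*	cb	3	apo	A7	T1	Chao1818	Japan	l
22	P. boninensis		P. boninensis x unknown	A1A7D5	W2T1T7	cb	3	apo	A7	T1	Chao1819	Japan	l
23	P. confusa	Y				cc		apo			Lu32448	Sri Lanka	l
24	P. aff. confusa			F1F1	Y73Y73	cu		apo	F1	Y73	CRFJ FN 402	Nepal	l
25	P. aff. confusa			F1F2				apo	F1	Y73	CRFJ 34,934	India	l
26	P. fauriei	Y	P. minor x P. latipinna	A1A6D7	W5T1*	cf	3	apo	A1 or A6	T1	Chao2082	Japan, Taiwan	l
27	P. fauriei	Y	P. minor x P. latipinna	A1D7*	W5T1*	cf	3	apo	A1	T1	Yang191005005	Taiwan	l
28	P. fauriei	Y	P. minor x P. latipinna	A6D7	W5T1	cf	2	apo	A6	T1	Chao2668	Taiwan	l
29	P. fauriei	Y	P. minor x P. latipinna	A6D7*	W5T1*	cf	3	apo	A6	T1	Chao2667	China, Japan, Taiwan	l
30	P. fauriei			A3A5D7	W5T1*	cf	3	apo	A3 or A5	T1	Chao2051	Japan	l
31	P. fauriei			A11D32*	W5T1*	cf	3	apo	A?	T1	Chao2805	Taiwan	l
32	P. fauriei		P. minor x P. latipinna	A1A13D7	W5T1	cf		apo	A1	T1	Chao2790	Taiwan	l
33	P. cf. fauriei		P. oshimensis var. oshimensis x P. latipinna	A4D7	W5T1	cf	2	apo	A4	T1	Chao2155	Taiwan	l
34	P. cf. fauriei		P. oshimensis var. oshimensis x P. latipinna	A4D7*	T1T4W23	cf	3	apo	A4	T1	Chao2156	Taiwan	l
35	P. cf. fauriei			A5A12D8	W5T1T4	cf	3	apo	A5 or A12	T1 or T4	Wade3659-1	Japan	l
36	P. cf. fauriei			C1D1	V12X79	cs	2	apo	C1	X79	Chao2028	Japan	l
37	P. cf. fauriei		P. wulaiensis x P. latipinna	D4D7	W28W23	cy	2	apo	D4	W28	Chao2035	Japan, Taiwan	l
38	P. cf. fauriei		P. wulaiensis x P. latipinna	D4D7	W29W23	cy	2	apo	D4	W29	Chao2553	Taiwan	l
39	P. cf. fauriei		P. wulaiensis x P. latipinna	D4D7	W5W28	cy		apo	D4	W28	Lu25409	China	l
40	P. kawabatae	Y		C3E2	V41V86	ce		apo	E2	V86	Lu22877	Taiwan	l
41	P. kawabatae			B4D2H4	S14W52X82	cs		apo	B4	X82	Chao2170	China	l
42	P. kawabatae			B4D5H1	W23X82Y11	cs	3	apo	B4	X82	Lu28259	Taiwan	l
43	P. kawabatae			B4H3	X82Y11	cs	2	apo	B4	X82	Lu28430B	Taiwan	l
44	P. kawabatae			C3D7E2	W23V41V86	ca		apo	D7	W23	Knapp 4145	Taiwan	l
45	P. kawabatae			C3D1	V12W75	cl	2	apo	D1	W75	Chao2022	Japan	l
46	P. kiuschiuensis	Y		C3H1	V12Y11	ck	2	apo	H1	Y11	Chao1852	China, Japan	l
47	P. kiuschiuensis			C3D4H1	W5W78Y11	cy	3	apo	D4	W78	Ebihara et al. 3240	Japan	l
48	P. kiuschiuensis			C3D4H1	W78V12Y11	cy	3	apo	D4	W78	Lu24743	China, Japan	l
49	P. kiuschiuensis			D4D7H1	V12Y11W29	ck		apo	H1	Y11	Chao2182	China	l
50	P. latipinna	Y		D7D7	W5W5	ca	2	apo	D7	W5	Chao2092	China, Taiwan	l
51	P. latipinna			D7D7	W2W2	ca		apo	D7	W2	ZXC001673	Taiwan	l
52	P. laurisilvicola	Y		A4A5D7	W30T1T4	cf	3	apo	A4	T1	Chao2555	Japan, Taiwan	l
53	P. laurisilvicola			A4A6D7	W5T1T4	cf	3	apo	A4 or A6	T1	Chao2528	Taiwan	l
54	P. laurisilvicola			A4A6D7	W30T1T4	cf	3	apo	A4 or A6	T1	Chao2891	Taiwan	l
55	P. minor	Y		A1A1	T1T1	cf	2	sex	A1	T1	Chao2078	Taiwan	l
56	P. minor	Y		A1A13	T1T1	cf	2	sex	A1	T1	Chao2647	Taiwan	l
57	P. minor	Y		A1A6	T31T31	cf'	2	sex	A1 or A6	T31	Chao2500	Taiwan	l
58	P. minor	Y		A6A6	T1T1	cf	2	sex	A6	T1	Hsu 8425	Taiwan	l
59	P. minor	Y		A6A6	T27T27	cf'	2	sex	A6	T27	Chao2653	Taiwan	l
60	P. natiensis	Y	unknown x P. latipinna	C3D7	V12W23	cn	2	apo	C3	V12	Chao1842	Japan	l
61	P. natiensis			C3D4D7	V12W28W23	cy	3	apo	D4	W28	Chao2017	China, Japan	l
62	P. oshimensis var. oshimensis		P. oshimensis var. oshimensis x unknown	A4D1	T1W75	cf	2	apo	A4	T1	Chao1881	Japan	l
63	P. oshimensis var. oshimensis	Y		A4A4	T1T1	cf	2	sex	A4	T1	Kuo3445	Japan	l
64	P. oshimensis var. paraemeiensis	Y				cs		apo			Zhang et al.20100430109	China	l
65	P. pseudowulaiensis			D1D5	W5W52	cw		apo	D5	W5	Hsu 8437	Taiwan	l
66	P. pseudowulaiensis			D2D5	W52W23	cw	2	apo	D5	W23	Ko33986	China	l
67	P. pseudowulaiensis		P. wulaiensis x unknown	D4D5	W5W28	cy	2	apo	D4	W28	Wade2315	China, Taiwan	l
68	P. satsumana	Y		B1C3	V12X82	cs	2	apo	B1	X82	Chao1925	Japan	l
69	P. setulosocostulata	Y		D4H4H10	W52Y11W89	ch	3	apo	H4	Y11	Chao2526	Taiwan	l
70	P. setulosocostulata			B2H3H5	X82Y11	ch		apo	H3	Y11	Chao1363	China	l
71	P. wulaiensis	Y		D2D4	W52W75	cd	2	apo	D2	W52	Hsu9088	Taiwan	l
72	P. wulaiensis			D4D4	W78W78	cy	2	apo	D4	W75	Ebihara et al. 3234	Japan	l
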