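index	label_value	abbreviation	hemisphere	lobe
1	2001	PreCG	left	frontal
2	2002	PreCG	right	frontal
3	2101	SFGdor	left	frontal
4	2102	SFGdor	right	frontal
5	2111	ORBsup	left	frontal
6	2112	ORBsup	right	frontal
7	2201	MFG	left	frontal
8	2202	MFG	right	frontal
9	2211	ORBmid	left	frontal
10	2212	ORBmid	right	frontal
11	2301	IFGoperc	left	frontal
12	2302	IFGoperc	right	frontal
13	2311	IFGtriang	left	frontal
14	2312	IFGtriang	right	frontal
15	2321	ORBinf	left	frontal
16	2322	ORBinf	right	frontal
17	2331	ROL	left	frontal
18	2332	ROL	right	frontal
19	2401	SMA	left	frontal
20	2402	SMA	right	frontal
21	2501	OLF	left	frontal
22	2502	OLF	right	frontal
23	2601	SFGmed	left	frontal
24	2602	SFGmed	right	frontal
25	2611	ORBsupmed	left	frontal
26	2612	ORBsupmed	right	frontal
27	2701	REC	left	frontal
28	2702	REC	right	frontal
29	3001	INS	left	limbic
30	3002	INS	right	limbic
31	4001	ACG	left	limbic
32	4002	ACG	right	limbic
33	4011	DCG	left	limbic
34	4012	DCG	right	limbic
35	4021	PCG	left	limbic
36	4022	PCG	right	limbic
37	4101	HIP	left	limbic
38	4102	HIP	right	limbic
39	4111	PHG	left	limbic
40	4112	PHG	right	limbic
41	4201	AMYG	left	limbic
42	4202	AMYG	right	limbic
43	5001	CAL	left	occipital
44	5002	CAL	right	occipital
45	5011	CUN	left	occipital
46	5012	CUN	right	occipital
47	5021	LING	left	occipital
48	5022	LING	right	occipital
49	5101	SOG	left	occipital
50	5102	SOG	right	occipital
51	5201	MOG	left	occipital
52	5202	MOG	right	occipital
53	5301	IOG	left	occipital
54	5302	IOG	right	occipital
55	5401	FFG	left	occipital
56	5402	FFG	right	occipital
57	6001	PoCG	left	parietal
58	6002	PoCG	right	parietal
59	6101	SPG	left	parietal
60	6102	SPG	right	parietal
61	6201	IPL	left	parietal
62	6202	IPL	right	parietal
63	6211	SMG	left	parietal
64	6212	SMG	right	parietal
65	6221	ANG	left	parietal
66	6222	ANG	right	parietal
67	6301	PCUN	left	parietal
68	6302	PCUN	right	parietal
69	6401	PCL	left	frontal
70	6402	PCL	right	frontal
71	7001	CAU	left	subcortical
72	7002	CAU	right	subcortical
73	7011	PUT	left	subcortical
74	7012	PUT	right	subcortical
75	7021	PAL	left	subcortical
76	7022	PAL	right	subcortical
77	7101	THA	left	subcortical
78	7102	THA	right	subcortical
79	8101	HES	left	temporal
80	8102	HES	right	temporal
81	8111	STG	left	temporal
82	8112	STG	right	temporal
83	8121	TPOsup	left	temporal
84	8122	TPOsup	right	temporal
85	8201	MTG	left	temporal
86	8202	MTG	right	temporal
87	8211	TPOmid	left	temporal
88	8212	TPOmid	right	temporal
89	8301	ITG	left	temporal
90	8302	ITG	right	temporal
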