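index	name	hemisphere	network
0	LH_Visual_1	left	Visual
1	LH_Visual_2	left	Visual
2	LH_Visual_3	left	Visual
3	LH_Visual_4	left	Visual
4	LH_Visual_5	left	Visual
5	LH_Visual_6	left	Visual
6	LH_Visual_7	left	Visual
7	LH_Visual_8	left	Visual
8	LH_Visual_9	left	Visual
9	LH_SomMot_1	left	SomMot
10	LH_SomMot_2	left	SomMot
11	LH_SomMot_3	left	SomMot
12	LH_SomMot_4	left	SomMot
13	LH_SomMot_5	left	SomMot
14	LH_SomMot_6	left	SomMot
15	LH_DorsalAttn_1	left	DorsalAttn
16	LH_DorsalAttn_2	left	DorsalAttn
17	LH_DorsalAttn_3	left	DorsalAttn
18	LH_DorsalAttn_4	left	DorsalAttn
19	LH_DorsalAttn_5	left	DorsalAttn
20	LH_DorsalAttn_6	left	DorsalAttn
21	LH_DorsalAttn_7	left	DorsalAttn
22	LH_DorsalAttn_8	left	DorsalAttn
23	LH_Salience_1	left	Salience
24	LH_Salience_2	left	Salience
25	LH_Salience_3	left	Salience
26	LH_Salience_4	left	Salience
27	LH_Salience_5	left	Salience
28	LH_Salience_6	left	Salience
29	LH_Salience_7	left	Salience
30	LH_Limbic_1	left	Limbic
31	LH_Limbic_2	left	Limbic
32	LH_Limbic_3	left	Limbic
33	LH_Limbic_4	left	Limbic
34	LH_Limbic_5	left	Limbic
35	LH_Control_1	left	Control
36	LH_Control_2	left	Control
37	LH_Control_3	left	Control
38	LH_Control_4	left	Control
39	LH_Default_1	left	Default
40	LH_Default_2	left	Default
41	LH_Default_3	left	Default
42	LH_Default_4	left	Default
43	LH_Default_5	left	Default
44	LH_Default_6	left	Default
45	LH_Default_7	left	Default
46	LH_Default_8	left	Default
47	LH_Default_9	left	Default
48	LH_Default_10	left	Default
49	LH_Default_11	left	Default
50	RH_Visual_1	right	Visual
51	RH_Visual_2	right	Visual
52	RH_Visual_3	right	Visual
53	RH_Visual_4	right	Visual
54	RH_Visual_5	right	Visual
55	RH_Visual_6	right	Visual
56	RH_Visual_7	right	Visual
57	RH_Visual_8	right	Visual
58	RH_SomMot_1	right	SomMot
59	RH_SomMot_2	right	SomMot
60	RH_SomMot_3	right	SomMot
61	RH_SomMot_4	right	SomMot
62	RH_SomMot_5	right	SomMot
63	RH_SomMot_6	right	SomMot
64	RH_SomMot_7	right	SomMot
65	RH_SomMot_8	right	SomMot
66	RH_DorsalAttn_1	right	DorsalAttn
67	RH_DorsalAttn_2	right	DorsalAttn
68	RH_DorsalAttn_3	right	DorsalAttn
69	RH_DorsalAttn_4	right	DorsalAttn
70	RH_DorsalAttn_5	right	DorsalAttn
71	RH_DorsalAttn_6	right	DorsalAttn
72	RH_DorsalAttn_7	right	DorsalAttn
73	RH_Salience_1	right	Salience
74	RH_Salience_2	right	Salience
75	RH_Salience_3	right	Salience
76	RH_Salience_4	right	Salience
77	RH_Salience_5	right	Salience
78	RH_Salience_6	right	Salience
79	RH_Limbic_1	right	Limbic
80	RH_Limbic_2	right	Limbic
81	RH_Limbic_3	right	Limbic
82	RH_Limbic_4	right	Limbic
83	RH_Limbic_5	right	Limbic
84	RH_Control_1	right	Control
85	RH_Control_2	right	Control
86	RH_Control_3	right	Control
87	RH_Control_4	right	Control
88	RH_Control_5	right	Control
89	RH_Control_6	right	Control
90	RH_Control_7	right	Control
91	RH_Control_8	right	Control
92	RH_Control_9	right	Control
93	RH_Default_1	right	Default
94	RH_Default_2	right	Default
95	RH_Default_3	right	Default
96	RH_Default_4	right	Default
97	RH_Default_5	right	Default
98	RH_Default_6	right	Default
99	RH_Default_7	right	Default
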