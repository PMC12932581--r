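index	label
1	Precentral.L
2	Precentral.R
3	Frontal.Sup.L
4	Frontal.Sup.R
5	Frontal.Mid.L
6	Frontal.Mid.R
7	Frontal.Inf.Oper.L
8	Frontal.Inf.Oper.R
9	Frontal.Inf.Tri.L
10	Frontal.Inf.Tri.R
11	Frontal.Inf.Orb.L
12	Frontal.Inf.Orb.R
13	Rolandic.Oper.L
14	Rolandic.Oper.R
15	Supp.Motor.Area.L
16	Supp.Motor.Area.R
17	Olfactory.L
18	Olfactory.R
19	Frontal.Sup.Medial.L
20	Frontal.Sup.Medial.R
21	Frontal.Med.Orb.L
22	Frontal.Med.Orb.R
23	Rectus.L
24	Rectus.R
25	OFCmed.L
26	OFCmed.R
27	OFCant.L
28	OFCant.R
29	OFCpost.L
30	OFCpost.R
31	OFClat.L
32	OFClat.R
33	Insula.L
34	Insula.R
35	ACC.Sub.L
36	ACC.Sub.R
37	ACC.Pre.L
38	ACC.Pre.R
39	ACC.Sup.L
40	ACC.Sup.R
41	Cingulate.Mid.L
42	Cingulate.Mid.R
43	Cingulate.Post.L
44	Cingulate.Post.R
45	Hippocampus.L
46	Hippocampus.R
47	ParaHippocampal.L
48	ParaHippocampal.R
49	Amygdala.L
50	Amygdala.R
51	Calcarine.L
52	Calcarine.R
53	Cuneus.L
54	Cuneus.R
55	Lingual.L
56	Lingual.R
57	Occipital.Sup.L
58	Occipital.Sup.R
59	Occipital.Mid.L
60	Occipital.Mid.R
61	Occipital.Inf.L
62	Occipital.Inf.R
63	Fusiform.L
64	Fusiform.R
65	Postcentral.L
66	Postcentral.R
67	Parietal.Sup.L
68	Parietal.Sup.R
69	Parietal.Inf.L
70	Parietal.Inf.R
71	SupraMarginal.L
72	SupraMarginal.R
73	Angular.L
74	Angular.R
75	Precuneus.L
76	Precuneus.R
77	Paracentral.Lobule.L
78	Paracentral.Lobule.R
79	Caudate.L
80	Caudate.R
81	Putamen.L
82	Putamen.R
83	Pallidum.L
84	Pallidum.R
85	Heschl.L
86	Heschl.R
87	Temporal.Sup.L
88	Temporal.Sup.R
89	Temporal.Pole.Sup.L
90	Temporal.Pole.Sup.R
91	Temporal.Mid.L
92	Temporal.Mid.R
93	Temporal.Pole.Mid.L
94	Temporal.Pole.Mid.R
95	Temporal.Inf.L
96	Temporal.Inf.R
97	Cerebellum.Crus1.L
98	Cerebellum.Crus1.R
99	Cerebellum.Crus2.L
100	Cerebellum.Crus2.R
101	Cerebellum.3.L
102	Cerebellum.3.R
103	Cerebellum.4.5.L
104	Cerebellum.4.5.R
105	Cerebellum.6.L
106	Cerebellum.6.R
107	Cerebellum.7b.L
108	Cerebellum.7b.R
109	Cerebellum.8.L
110	Cerebellum.8.R
111	Cerebellum.9.L
112	Cerebellum.9.R
113	Cerebellum.10.L
114	Cerebellum.10.R
115	Vermis.1.2
116	Vermis.3
117	Vermis.4.5
118	Vermis.6
119	Vermis.7
120	Vermis.8
121	Vermis.9
122	Thal.AV.L
123	Thal.AV.R
124	Thal.LP.L
125	Thal.LP.R
126	Thal.VA.L
127	Thal.VA.R
128	Thal.VL.L
129	Thal.VL.R
130	Thal.VPL.L
131	Thal.VPL.R
132	Thal.IL.L
133	Thal.IL.R
134	Thal.Re.L
135	Thal.Re.R
136	Thal.MDm.L
137	Thal.MDm.R
138	Thal.MDl.L
139	Thal.MDl.R
140	Thal.LGN.L
141	Thal.LGN.R
142	Thal.MGN.L
143	Thal.MGN.R
144	Thal.PuA.L
145	Thal.PuA.R
146	Thal.PuM.L
147	Thal.PuM.R
148	Thal.PuL.L
149	Thal.PuL.R
150	Thal.PuI.L
151	Thal.PuI.R
152	N.Acc.L
153	N.Acc.R
154	VTA.L
155	VTA.R
156	SN.pc.L
157	SN.pc.R
158	SN.pr.L
159	SN.pr.R
160	Red.N.L
161	Red.N.R
162	LC.L
163	LC.R
164	Vermis.10
165	Raphe.D
166	Raphe.M
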