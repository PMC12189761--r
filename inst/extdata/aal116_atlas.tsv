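leaf_id	leaf_name	atlas_label	hemisphere
0	Precentral.L	1	left
1	Precentral.R	2	right
2	Frontal_Sup.L	3	left
3	Frontal_Sup.R	4	right
4	Frontal_Sup_Orb.L	5	left
5	Frontal_Sup_Orb.R	6	right
6	Frontal_Mid.L	7	left
7	Frontal_Mid.R	8	right
8	Frontal_Mid_Orb.L	9	left
9	Frontal_Mid_Orb.R	10	right
10	Frontal_Inf_Oper.L	11	left
11	Frontal_Inf_Oper.R	12	right
12	Frontal_Inf_Tri.L	13	left
13	Frontal_Inf_Tri.R	14	right
14	Frontal_Inf_Orb.L	15	left
15	Frontal_Inf_Orb.R	16	right
16	Rolandic_Oper.L	17	left
17	Rolandic_Oper.R	18	right
18	Supp_Motor_Area.L	19	left
19	Supp_Motor_Area.R	20	right
20	Olfactory.L	21	left
21	Olfactory.R	22	right
22	Frontal_Sup_Medial.L	23	left
23	Frontal_Sup_Medial.R	24	right
24	Frontal_Med_Orb.L	25	left
25	Frontal_Med_Orb.R	26	right
26	Rectus.L	27	left
27	Rectus.R	28	right
28	Insula.L	29	left
29	Insula.R	30	right
30	Cingulum_Ant.L	31	left
31	Cingulum_Ant.R	32	right
32	Cingulum_Mid.L	33	left
33	Cingulum_Mid.R	34	right
34	Cingulum_Post.L	35	left
35	Cingulum_Post.R	36	right
36	Hippocampus.L	37	left
37	Hippocampus.R	38	right
38	ParaHippocampal.L	39	left
39	ParaHippocampal.R	40	right
40	Amygdala.L	41	left
41	Amygdala.R	42	right
42	Calcarine.L	43	left
43	Calcarine.R	44	right
44	Cuneus.L	45	left
45	Cuneus.R	46	right
46	Lingual.L	47	left
47	Lingual.R	48	right
48	Occipital_Sup.L	49	left
49	Occipital_Sup.R	50	right
50	Occipital_Mid.L	51	left
51	Occipital_Mid.R	52	right
52	Occipital_Inf.L	53	left
53	Occipital_Inf.R	54	right
54	Fusiform.L	55	left
55	Fusiform.R	56	right
56	Postcentral.L	57	left
57	Postcentral.R	58	right
58	Parietal_Sup.L	59	left
59	Parietal_Sup.R	60	right
60	Parietal_Inf.L	61	left
61	Parietal_Inf.R	62	right
62	SupraMarginal.L	63	left
63	SupraMarginal.R	64	right
64	Angular.L	65	left
65	Angular.R	66	right
66	Precuneus.L	67	left
67	Precuneus.R	68	right
68	Paracentral_Lobule.L	69	left
69	Paracentral_Lobule.R	70	right
70	Caudate.L	71	left
71	Caudate.R	72	right
72	Putamen.L	73	left
73	Putamen.R	74	right
74	Pallidum.L	75	left
75	Pallidum.R	76	right
76	Thalamus.L	77	left
77	Thalamus.R	78	right
78	Heschl.L	79	left
79	Heschl.R	80	right
80	Temporal_Sup.L	81	left
81	Temporal_Sup.R	82	right
82	Temporal_Pole_Sup.L	83	left
83	Temporal_Pole_Sup.R	84	right
84	Temporal_Mid.L	85	left
85	Temporal_Mid.R	86	right
86	Temporal_Pole_Mid.L	87	left
87	Temporal_Pole_Mid.R	88	right
88	Temporal_Inf.L	89	left
89	Temporal_Inf.R	90	right
90	Cerebelum_Crus1.L	91	left
91	Cerebelum_Crus1.R	92	right
92	Cerebelum_Crus2.L	93	left
93	Cerebelum_Crus2.R	94	right
94	Cerebelum_3.L	95	left
95	Cerebelum_3.R	96	right
96	Cerebelum_4_5.L	97	left
97	Cerebelum_4_5.R	98	right
98	Cerebelum_6.L	99	left
99	Cerebelum_6.R	100	right
100	Cerebelum_7b.L	101	left
101	Cerebelum_7b.R	102	right
102	Cerebelum_8.L	103	left
103	Cerebelum_8.R	104	right
104	Cerebelum_9.L	105	left
105	Cerebelum_9.R	106	right
106	Cerebelum_10.L	107	left
107	Cerebelum_10.R	108	right
108	Vermis_1_2	109	midline
109	Vermis_3	110	midline
110	Vermis_4_5	111	midline
111	Vermis_6	112	midline
112	Vermis_7	113	midline
113	Vermis_8	114	midline
114	Vermis_9	115	midline
115	Vermis_10	116	midline
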