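roi_id	x	y	z	network
1	-72	-84	-48	Sal
2	-48	-84	-48	Hand
3	-24	-84	-48	Hand
4	0	-84	-48	Hand
5	24	-84	-48	FP
6	48	-84	-48	Vis
7	72	-84	-48	DMN
8	-72	-60	-48	DMN
9	-48	-60	-48	DMN
10	-24	-60	-48	Aud
11	0	-60	-48	DMN
12	24	-60	-48	unassigned
13	48	-60	-48	CO
14	72	-60	-48	unassigned
15	-72	-36	-48	DMN
16	-48	-36	-48	Sal
17	-24	-36	-48	Aud
18	0	-36	-48	Sal
19	24	-36	-48	unassigned
20	48	-36	-48	Hand
21	72	-36	-48	unassigned
22	-72	-12	-48	FP
23	-48	-12	-48	Vis
24	-24	-12	-48	DMN
25	0	-12	-48	unassigned
26	24	-12	-48	Aud
27	48	-12	-48	Hand
28	72	-12	-48	unassigned
29	-72	12	-48	DAN
30	-48	12	-48	unassigned
31	-24	12	-48	FP
32	0	12	-48	unassigned
33	24	12	-48	unassigned
34	48	12	-48	unassigned
35	72	12	-48	DMN
36	-72	36	-48	DAN
37	-48	36	-48	DMN
38	-24	36	-48	DMN
39	0	36	-48	DMN
40	24	36	-48	Vis
41	48	36	-48	DMN
42	72	36	-48	Sal
43	-72	60	-48	unassigned
44	-48	60	-48	FP
45	-24	60	-48	Sal
46	0	60	-48	Sal
47	24	60	-48	unassigned
48	48	60	-48	DAN
49	72	60	-48	Mouth
50	-72	84	-48	Vis
51	-48	84	-48	unassigned
52	-24	84	-48	CO
53	0	84	-48	Vis
54	24	84	-48	DMN
55	48	84	-48	Vis
56	72	84	-48	DMN
57	-72	-84	-24	unassigned
58	-48	-84	-24	DAN
59	-24	-84	-24	unassigned
60	0	-84	-24	VAN
61	24	-84	-24	FP
62	48	-84	-24	Aud
63	72	-84	-24	CO
64	-72	-60	-24	FP
65	-48	-60	-24	Sal
66	-24	-60	-24	Vis
67	0	-60	-24	Hand
68	24	-60	-24	Vis
69	48	-60	-24	Hand
70	72	-60	-24	FP
71	-72	-36	-24	Aud
72	-48	-36	-24	VAN
73	-24	-36	-24	unassigned
74	0	-36	-24	FP
75	24	-36	-24	DMN
76	48	-36	-24	DMN
77	72	-36	-24	DMN
78	-72	-12	-24	DMN
79	-48	-12	-24	Sal
80	-24	-12	-24	Hand
81	0	-12	-24	FP
82	24	-12	-24	FP
83	48	-12	-24	DMN
84	72	-12	-24	Vis
85	-72	12	-24	Aud
86	-48	12	-24	Hand
87	-24	12	-24	FP
88	0	12	-24	Sal
89	24	12	-24	DMN
90	48	12	-24	DMN
91	72	12	-24	Hand
92	-72	36	-24	CO
93	-48	36	-24	Hand
94	-24	36	-24	FP
95	0	36	-24	Vis
96	24	36	-24	FP
97	48	36	-24	DMN
98	72	36	-24	Mouth
99	-72	60	-24	Vis
100	-48	60	-24	DMN
101	-24	60	-24	DAN
102	0	60	-24	Aud
103	24	60	-24	unassigned
104	48	60	-24	Hand
105	72	60	-24	CO
106	-72	84	-24	DAN
107	-48	84	-24	FP
108	-24	84	-24	DMN
109	0	84	-24	Hand
110	24	84	-24	Vis
111	48	84	-24	unassigned
112	72	84	-24	Hand
113	-72	-84	0	unassigned
114	-48	-84	0	DMN
115	-24	-84	0	Mouth
116	0	-84	0	FP
117	24	-84	0	Aud
118	48	-84	0	Hand
119	72	-84	0	VAN
120	-72	-60	0	unassigned
121	-48	-60	0	FP
122	-24	-60	0	DMN
123	0	-60	0	Sal
124	24	-60	0	Sal
125	48	-60	0	Vis
126	72	-60	0	unassigned
127	-72	-36	0	Sal
128	-48	-36	0	Hand
129	-24	-36	0	Hand
130	0	-36	0	CO
131	24	-36	0	DAN
132	48	-36	0	Vis
133	72	-36	0	Sal
134	-72	-12	0	DMN
135	-48	-12	0	CO
136	-24	-12	0	unassigned
137	0	-12	0	DMN
138	24	-12	0	Vis
139	48	-12	0	unassigned
140	72	-12	0	Vis
141	-72	12	0	FP
142	-48	12	0	Aud
143	-24	12	0	DMN
144	0	12	0	CO
145	24	12	0	unassigned
146	48	12	0	DMN
147	72	12	0	Hand
148	-72	36	0	Hand
149	-48	36	0	unassigned
150	-24	36	0	Vis
151	0	36	0	Hand
152	24	36	0	DMN
153	48	36	0	DMN
154	72	36	0	DMN
155	-72	60	0	unassigned
156	-48	60	0	DMN
157	-24	60	0	unassigned
158	0	60	0	unassigned
159	24	60	0	Vis
160	48	60	0	CO
161	72	60	0	DMN
162	-72	84	0	unassigned
163	-48	84	0	Hand
164	-24	84	0	Vis
165	0	84	0	Aud
166	24	84	0	unassigned
167	48	84	0	FP
168	72	84	0	DMN
169	-72	-84	24	unassigned
170	-48	-84	24	CO
171	-24	-84	24	DAN
172	0	-84	24	unassigned
173	24	-84	24	DMN
174	48	-84	24	DMN
175	72	-84	24	DMN
176	-72	-60	24	DMN
177	-48	-60	24	Hand
178	-24	-60	24	CO
179	0	-60	24	unassigned
180	24	-60	24	Hand
181	48	-60	24	Aud
182	72	-60	24	unassigned
183	-72	-36	24	DMN
184	-48	-36	24	Hand
185	-24	-36	24	unassigned
186	0	-36	24	DMN
187	24	-36	24	unassigned
188	48	-36	24	Hand
189	72	-36	24	unassigned
190	-72	-12	24	DMN
191	-48	-12	24	unassigned
192	-24	-12	24	DMN
193	0	-12	24	FP
194	24	-12	24	unassigned
195	48	-12	24	Vis
196	72	-12	24	DMN
197	-72	12	24	DMN
198	-48	12	24	unassigned
199	-24	12	24	CO
200	0	12	24	Mouth
201	24	12	24	DAN
202	48	12	24	Hand
203	72	12	24	Vis
204	-72	36	24	unassigned
205	-48	36	24	Sal
206	-24	36	24	VAN
207	0	36	24	Vis
208	24	36	24	DMN
209	48	36	24	Vis
210	72	36	24	CO
211	-72	60	24	VAN
212	-48	60	24	FP
213	-24	60	24	DMN
214	0	60	24	unassigned
215	24	60	24	VAN
216	48	60	24	DMN
217	72	60	24	unassigned
218	-72	84	24	Vis
219	-48	84	24	VAN
220	-24	84	24	unassigned
221	0	84	24	unassigned
222	24	84	24	unassigned
223	48	84	24	DAN
224	72	84	24	Sal
225	-72	-84	48	Vis
226	-48	-84	48	Vis
227	-24	-84	48	DMN
228	0	-84	48	FP
229	24	-84	48	DMN
230	48	-84	48	DMN
231	72	-84	48	Hand
232	-72	-60	48	Vis
233	-48	-60	48	Vis
234	-24	-60	48	VAN
235	0	-60	48	Aud
236	24	-60	48	unassigned
237	48	-60	48	FP
238	72	-60	48	unassigned
239	-72	-36	48	VAN
240	-48	-36	48	FP
241	-24	-36	48	Vis
242	0	-36	48	DMN
243	24	-36	48	Vis
244	48	-36	48	DAN
245	72	-36	48	DMN
246	-72	-12	48	DMN
247	-48	-12	48	Sal
248	-24	-12	48	Sal
249	0	-12	48	FP
250	24	-12	48	unassigned
251	48	-12	48	DMN
252	72	-12	48	CO
253	-72	12	48	Sal
254	-48	12	48	Vis
255	-24	12	48	DMN
256	0	12	48	unassigned
257	24	12	48	DMN
258	48	12	48	DMN
259	72	12	48	Hand
260	-72	36	48	Hand
261	-48	36	48	Aud
262	-24	36	48	Mouth
263	0	36	48	Hand
264	24	36	48	FP
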