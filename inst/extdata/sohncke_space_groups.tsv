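number	symbol	centering	n_ops_conventional	multiplicity	n_ops_primitive
1	P 1	P	1	1	1
3	P 1 2 1	P	2	1	2
4	P 1 21 1	P	2	1	2
5	C 1 2 1	C	4	2	2
16	P 2 2 2	P	4	1	4
17	P 2 2 21	P	4	1	4
18	P 21 21 2	P	4	1	4
19	P 21 21 21	P	4	1	4
20	C 2 2 21	C	8	2	4
21	C 2 2 2	C	8	2	4
22	F 2 2 2	F	16	4	4
23	I 2 2 2	I	8	2	4
24	I 21 21 21	I	8	2	4
75	P 4	P	4	1	4
76	P 41	P	4	1	4
77	P 42	P	4	1	4
78	P 43	P	4	1	4
79	I 4	I	8	2	4
80	I 41	I	8	2	4
89	P 4 2 2	P	8	1	8
90	P 4 21 2	P	8	1	8
91	P 41 2 2	P	8	1	8
92	P 41 21 2	P	8	1	8
93	P 42 2 2	P	8	1	8
94	P 42 21 2	P	8	1	8
95	P 43 2 2	P	8	1	8
96	P 43 21 2	P	8	1	8
97	I 4 2 2	I	16	2	8
98	I 41 2 2	I	16	2	8
143	P 3	P	3	1	3
144	P 31	P	3	1	3
145	P 32	P	3	1	3
146	R 3:H	R_hex	9	3	3
146	R 3:R	R_rhomb	3	1	3
149	P 3 1 2	P	6	1	6
150	P 3 2 1	P	6	1	6
151	P 31 1 2	P	6	1	6
152	P 31 2 1	P	6	1	6
153	P 32 1 2	P	6	1	6
154	P 32 2 1	P	6	1	6
155	R 3 2:H	R_hex	18	3	6
155	R 3 2:R	R_rhomb	6	1	6
168	P 6	P	6	1	6
169	P 61	P	6	1	6
170	P 65	P	6	1	6
171	P 62	P	6	1	6
172	P 64	P	6	1	6
173	P 63	P	6	1	6
177	P 6 2 2	P	12	1	12
178	P 61 2 2	P	12	1	12
179	P 65 2 2	P	12	1	12
180	P 62 2 2	P	12	1	12
181	P 64 2 2	P	12	1	12
182	P 63 2 2	P	12	1	12
195	P 2 3	P	12	1	12
196	F 2 3	F	48	4	12
197	I 2 3	I	24	2	12
198	P 21 3	P	12	1	12
199	I 21 3	I	24	2	12
207	P 4 3 2	P	24	1	24
208	P 42 3 2	P	24	1	24
209	F 4 3 2	F	96	4	24
210	F 41 3 2	F	96	4	24
211	I 4 3 2	I	48	2	24
212	P 43 3 2	P	24	1	24
213	P 41 3 2	P	24	1	24
214	I 41 3 2	I	48	2	24
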