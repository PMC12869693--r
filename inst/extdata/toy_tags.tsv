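row	v	o	b
0	0	1	0
1	0	1	0
2	0	1	0
3	0	1	0
4	0	1	0
5	0	1	0
6	8	2	0
7	8	2	0
8	8	2	0
9	8	2	1
10	8	2	1
11	8	2	1
12	1	1	1
13	1	1	1
14	1	1	1
15	1	4	0
16	1	4	0
17	7	0	1
18	7	0	1
19	7	0	1
20	4	0	0
21	4	0	0
22	4	0	0
23	7	2	0
24	7	2	0
25	7	2	0
26	3	0	1
27	1	4	0
28	1	2	1
29	1	2	1
30	1	2	1
31	4	3	0
32	4	3	0
33	4	3	0
34	6	0	1
35	5	1	1
36	6	0	1
37	1	1	0
38	1	1	0
39	1	1	0
40	1	4	1
41	1	4	1
42	1	4	1
43	8	1	1
44	8	1	1
45	8	1	1
46	2	0	0
47	2	0	0
48	7	1	0
49	7	1	0
50	7	1	0
51	7	0	0
52	7	0	0
53	7	0	0
54	5	1	0
55	4	1	1
56	4	1	1
57	4	1	1
58	4	2	1
59	7	1	1
60	7	1	1
61	7	1	1
62	4	2	1
63	4	2	1
64	8	1	0
65	8	1	0
66	8	1	0
67	4	2	0
68	4	2	0
69	4	2	0
70	7	4	1
71	5	0	1
72	7	4	1
73	1	0	0
74	1	0	0
75	1	0	0
76	4	1	0
77	4	1	0
78	4	1	0
79	7	3	1
80	7	4	1
81	7	3	1
82	7	3	1
83	2	0	1
84	2	0	1
85	7	3	0
86	7	3	0
87	7	3	0
88	1	0	1
89	1	0	1
90	1	0	1
91	1	3	0
92	1	3	0
93	3	0	0
94	4	3	1
95	1	3	0
96	1	3	1
97	1	3	1
98	1	3	1
99	8	0	1
100	8	0	1
101	8	0	1
102	6	0	0
103	6	0	0
104	5	0	0
105	4	0	1
106	4	0	1
107	4	0	1
108	8	0	0
109	8	0	0
110	8	0	0
111	7	2	1
112	7	2	1
113	7	2	1
114	4	3	1
115	4	3	1
116	1	2	0
117	1	2	0
118	1	2	0
119	7	4	0
120	7	4	0
121	7	4	0
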