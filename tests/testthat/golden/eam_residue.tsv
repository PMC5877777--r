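residue	unit	kappa	dG_f	ddG_A5	ddG_A23
1	1	5.40854	-1	0.72	0
2	1	5.40854	-1	0.72	0
3	1	5.40854	-1	0.72	0
4	1	5.40854	-1	0.72	0
5	1	5.40854	-1	0.72	0
6	1	5.40854	-1	0.72	0
7	1	5.40854	-1	0.72	0
8	1	5.40854	-1	0.72	0
9	2	5.40854	-1	0	0
10	2	5.40854	-1	0	0
11	2	5.40854	-1	0	0
12	2	5.40854	-1	0	0
13	2	5.40854	-1	0	0
14	2	5.40854	-1	0	0
15	2	5.40854	-1	0	0
16	2	5.40854	-1	0	0
17	3	5.40854	-1	0	0.48
18	3	5.40854	-1	0	0.48
19	3	5.40854	-1	0	0.48
20	3	5.40854	-1	0	0.48
21	3	5.40854	-1	0	0.48
22	3	5.40854	-1	0	0.48
23	3	5.40854	-1	0	0.48
24	3	5.40854	-1	0	0.48
25	4	5.40854	-1	0	0
26	4	5.40854	-1	0	0
27	4	5.40854	-1	0	0
28	4	5.40854	-1	0	0
29	4	5.40854	-1	0	0
30	4	5.40854	-1	0	0
31	4	5.40854	-1	0	0
32	4	5.40854	-1	0	0
33	5	5.40854	-1	0	0
34	5	5.40854	-1	0	0
35	5	5.40854	-1	0	0
36	5	5.40854	-1	0	0
37	5	5.40854	-1	0	0
38	5	5.40854	-1	0	0
39	5	5.40854	-1	0	0
40	5	5.40854	-1	0	0
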