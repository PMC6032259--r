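# SYNTHETIC stand-in for the 51-position AQP2 pore-residue mapping.
# The position count and the anchor rows (positions 10, 21, 23, 26, 30,
# 36, 41) are as documented for the aquaporin pore logo; the remaining
# residue numbers are synthetic placeholders and carry no biological
# meaning ("-" in the aa column).
position	resno	aa
1	83	-
2	51	-
3	87	-
4	55	-
5	90	-
6	58	-
7	94	-
8	61	-
9	91	-
10	64	G
11	162	-
12	97	-
13	165	-
14	69	-
15	73	-
16	101	-
17	104	-
18	163	-
19	66	-
20	159	-
21	71	V
22	105	-
23	68	N
24	166	-
25	109	-
26	168	V
27	112	-
28	170	-
29	74	-
30	187	R
31	174	-
32	116	-
33	119	-
34	176	-
35	178	-
36	181	C
37	120	-
38	182	-
39	121	-
40	186	-
41	180	G
42	124	-
43	188	-
44	127	-
45	192	-
46	131	-
47	195	-
48	134	-
49	199	-
50	138	-
51	203	-
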