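index	het_state	tcn	size	name
1	homdel	0	0-100kb	homdel:0:0-100kb
2	homdel	0	100kb-1Mb	homdel:0:100kb-1Mb
3	homdel	0	>1Mb	homdel:0:>1Mb
4	loh	1	0-100kb	loh:1:0-100kb
5	loh	1	100kb-1Mb	loh:1:100kb-1Mb
6	loh	1	1Mb-10Mb	loh:1:1Mb-10Mb
7	loh	1	10Mb-40Mb	loh:1:10Mb-40Mb
8	loh	1	>40Mb	loh:1:>40Mb
9	loh	2	0-100kb	loh:2:0-100kb
10	loh	2	100kb-1Mb	loh:2:100kb-1Mb
11	loh	2	1Mb-10Mb	loh:2:1Mb-10Mb
12	loh	2	10Mb-40Mb	loh:2:10Mb-40Mb
13	loh	2	>40Mb	loh:2:>40Mb
14	loh	3-4	0-100kb	loh:3-4:0-100kb
15	loh	3-4	100kb-1Mb	loh:3-4:100kb-1Mb
16	loh	3-4	1Mb-10Mb	loh:3-4:1Mb-10Mb
17	loh	3-4	10Mb-40Mb	loh:3-4:10Mb-40Mb
18	loh	3-4	>40Mb	loh:3-4:>40Mb
19	loh	5-8	0-100kb	loh:5-8:0-100kb
20	loh	5-8	100kb-1Mb	loh:5-8:100kb-1Mb
21	loh	5-8	1Mb-10Mb	loh:5-8:1Mb-10Mb
22	loh	5-8	10Mb-40Mb	loh:5-8:10Mb-40Mb
23	loh	5-8	>40Mb	loh:5-8:>40Mb
24	loh	9+	0-100kb	loh:9+:0-100kb
25	loh	9+	100kb-1Mb	loh:9+:100kb-1Mb
26	loh	9+	1Mb-10Mb	loh:9+:1Mb-10Mb
27	loh	9+	10Mb-40Mb	loh:9+:10Mb-40Mb
28	loh	9+	>40Mb	loh:9+:>40Mb
29	het	2	0-100kb	het:2:0-100kb
30	het	2	100kb-1Mb	het:2:100kb-1Mb
31	het	2	1Mb-10Mb	het:2:1Mb-10Mb
32	het	2	10Mb-40Mb	het:2:10Mb-40Mb
33	het	2	>40Mb	het:2:>40Mb
34	het	3-4	0-100kb	het:3-4:0-100kb
35	het	3-4	100kb-1Mb	het:3-4:100kb-1Mb
36	het	3-4	1Mb-10Mb	het:3-4:1Mb-10Mb
37	het	3-4	10Mb-40Mb	het:3-4:10Mb-40Mb
38	het	3-4	>40Mb	het:3-4:>40Mb
39	het	5-8	0-100kb	het:5-8:0-100kb
40	het	5-8	100kb-1Mb	het:5-8:100kb-1Mb
41	het	5-8	1Mb-10Mb	het:5-8:1Mb-10Mb
42	het	5-8	10Mb-40Mb	het:5-8:10Mb-40Mb
43	het	5-8	>40Mb	het:5-8:>40Mb
44	het	9+	0-100kb	het:9+:0-100kb
45	het	9+	100kb-1Mb	het:9+:100kb-1Mb
46	het	9+	1Mb-10Mb	het:9+:1Mb-10Mb
47	het	9+	10Mb-40Mb	het:9+:10Mb-40Mb
48	het	9+	>40Mb	het:9+:>40Mb
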