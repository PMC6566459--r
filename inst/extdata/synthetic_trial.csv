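subject_id,y,u,x
1,1.2186,1,0.9889
2,1.1007,1,0.3977
3,1.5146,1,0.1157
4,0.4884,1,0.0697
5,1.409,1,0.2437
6,-0.4015,1,0.792
7,3.1505,1,0.3401
8,0.5912,1,0.9721
9,1.9005,1,0.1659
10,2.7311,1,0.4591
11,1.5373,1,0.1717
12,1.7923,1,0.2315
13,0.3672,1,0.7728
14,3.5072,1,0.0963
15,2.5237,1,0.4534
16,2.281,1,0.0847
17,-1.5679,1,0.5607
18,2.1183,1,0.0087
19,0.166,1,0.9857
20,0.9001,1,0.3166
21,0.0764,1,0.6394
22,1.9592,1,0.2952
23,0.5437,1,0.9967
24,0.7048,1,0.906
25,0.319,1,0.9887
26,2.9092,1,0.0656
27,0.7692,1,0.627
28,2.9535,1,0.4905
29,1.2607,1,0.971
30,2.5006,1,0.3622
31,0.4326,1,0.68
32,0.8774,1,0.2637
33,1.1844,1,0.1857
34,0.9333,1,0.1851
35,0.1605,1,0.3793
36,-1.3258,1,0.847
37,0.911,1,0.4981
38,-0.5576,1,0.7906
39,-0.0624,1,0.8385
40,4.2227,1,0.4569
41,0.3426,0,0.7995
42,1.0042,0,0.3819
43,0.0292,0,0.7597
44,0.6066,0,0.4368
45,-0.7927,0,0.9042
46,0.6883,0,0.3195
47,0.6539,0,0.0826
48,-0.3046,0,0.8163
49,-1.7859,0,0.8985
50,0.5873,0,0.9665
51,1.6358,0,0.5731
52,-0.6454,0,0.7201
53,0.619,0,0.7741
54,0.2364,0,0.6278
55,0.8465,0,0.723
56,0.4264,0,0.3868
57,2.118,0,0.1628
58,-0.54,0,0.1872
59,0.5619,0,0.3912
60,0.8493,0,0.2739
61,1.5191,0,0.1919
62,0.5875,0,0.5044
63,-0.0793,0,0.7638
64,-1.1744,0,0.6937
65,0.3087,0,0.5441
66,-1.6039,0,0.6591
67,1.9913,0,0.4687
68,2.0232,0,0.4818
69,1.8401,0,0.3371
70,1.1201,0,0.4245
71,0.5737,0,0.287
72,0.4589,0,0.6012
73,0.645,0,0.8407
74,0.6115,0,0.6208
75,0.1108,0,0.1346
76,1.5439,0,0.5677
77,-0.2418,0,0.4434
78,2.1034,0,0.438
79,0.9828,0,0.6236
80,0.3043,0,0.9327
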