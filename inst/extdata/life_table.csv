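"age","qx"
18,8e-04
19,0.000854545454545455
20,0.000909090909090909
21,0.000963636363636364
22,0.00101818181818182
23,0.00107272727272727
24,0.00112727272727273
25,0.00118181818181818
26,0.00123636363636364
27,0.00129090909090909
28,0.00134545454545455
29,0.0014
30,0.00145454545454545
31,0.00150909090909091
32,0.00156363636363636
33,0.00161818181818182
34,0.00167272727272727
35,0.00172727272727273
36,0.00178181818181818
37,0.00183636363636364
38,0.00189090909090909
39,0.00194545454545455
40,0.002
41,0.002
42,0.002
43,0.002
44,0.002
45,0.00259367910930202
46,0.00282842712474619
47,0.00308442165081588
48,0.00336358566101486
49,0.00366801617281868
50,0.004
51,0.00436203093066103
52,0.00475682846001088
53,0.00518735821860404
54,0.00565685424949238
55,0.00616884330163176
56,0.00672717132202972
57,0.00733603234563737
58,0.008
59,0.00872406186132206
60,0.00951365692002177
61,0.0103747164372081
62,0.0113137084989848
63,0.0123376866032635
64,0.0134543426440594
65,0.0146720646912747
66,0.016
67,0.0174481237226441
68,0.0190273138400435
69,0.0207494328744162
70,0.0226274169979695
71,0.0246753732065271
72,0.0269086852881189
73,0.0293441293825495
74,0.032
75,0.0348962474452882
76,0.0380546276800871
77,0.0414988657488323
78,0.045254833995939
79,0.0493507464130541
80,0.0538173705762377
81,0.058688258765099
82,0.064
83,0.0697924948905765
84,0.0761092553601741
85,0.0829977314976646
86,0.0905096679918781
87,0.0987014928261082
88,0.107634741152475
89,0.117376517530198
90,0.128
91,0.139584989781153
92,0.152218510720348
93,0.165995462995329
94,0.181019335983756
95,0.197402985652216
96,0.215269482304951
97,0.234753035060396
98,0.256
99,0.279169979562306
100,1
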