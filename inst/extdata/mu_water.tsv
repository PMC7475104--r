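energy_kev	mu_per_cm
15	1.558
18	0.9811
20	0.751
22	0.62384
25	0.48641
28	0.39013
30	0.3411
33	0.30968
36	0.28353
40	0.2548
45	0.23585
50	0.2201
55	0.21191
60	0.2047
65	0.19908
70	0.19401
75	0.18941
80	0.1852
85	0.18157
90	0.17822
95	0.17511
100	0.1722
110	0.16699
120	0.16237
130	0.15823
140	0.1545
150	0.1511
160	0.14791
180	0.14227
200	0.1374
220	0.13276
240	0.12865
260	0.12499
280	0.12169
300	0.1187
325	0.11508
350	0.11183
375	0.10888
400	0.1062
450	0.10113
500	0.0968
550	0.09297
600	0.0896
700	0.08353
800	0.0786
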