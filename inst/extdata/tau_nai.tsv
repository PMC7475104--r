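energy_kev	tau_per_cm
15	253.89578
18	146.93043
20	107.11228
22	80.47504
25	54.84149
28	39.03509
30	31.73697
32	26.15046
33.1	23.629
33.2	133.4719
35	113.92
38	89.01298
42	65.92593
46	50.18
50	39.07456
55	29.3573
60	22.61259
65	17.78542
70	14.24
75	11.57765
80	9.53969
85	7.9533
90	6.70003
95	5.69683
100	4.88432
110	3.66966
120	2.82657
130	2.22318
140	1.78
150	1.44721
160	1.19246
180	0.8375
200	0.61054
220	0.45871
240	0.35332
260	0.2779
280	0.2225
300	0.1809
325	0.14574
350	0.11931
375	0.09903
400	0.0832
450	0.06053
500	0.04555
550	0.03521
600	0.02784
700	0.01836
800	0.0128
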