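read_count	log2_ratio
53	-1.9662
256	-2.0771
237	-1.0665
2265	-2.8202
118	-1.4196
1093	-2.7536
1040	-3.5252
51	-2.3462
85	-2.5209
730	-2.2307
132	-2.7763
83	-1.7463
608	-1.235
1271	-3.7411
520	-2.2343
310	-1.3771
43	0.0192
1014	-3.0484
68	-2.0867
447	-3.4916
69	-3.4628
226	-2.2325
126	-1.5272
308	-1.3326
368	-0.8454
496	-3.3834
862	-2.3567
156	-2.2024
102	-2.9713
185	-0.0699
234	-2.0148
1338	-3.4719
532	-1.8089
382	-2.1558
513	-2.0018
634	-1.6607
913	-2.7342
431	-1.6198
7363	-1.5288
670	-1.3252
659	-0.9627
397	-2.7023
68	-0.9978
35	-1.1877
181	-2.5221
1070	-0.6281
437	-2.4282
175	-0.5576
119	-2.1448
431	-1.8612
127	-2.0608
621	-2.2554
136	-3.7187
1625	-2.1148
409	-3.5863
200	-0.9693
190	-2.4452
81	0.2665
193	-1.7529
43	-1.9815
56	-1.8833
455	-3.4239
473	-0.3313
725	-1.3148
43	-2.983
939	-2.2794
2314	-2.2599
161	0.2626
100	-2.978
244	0.118
100	0.1427
143	-3.1624
94	-4.2355
80	-3.3401
2680	-0.1005
949	-3.695
452	-2.1876
817	-1.2716
136	-1.563
1213	0.2699
169	-4.0016
728	-0.0431
2552	-0.9772
29	-3.53
83	-0.9132
397	-2.8489
65	-2.792
486	-1.232
548	-3.063
163	0.1168
929	-1.5749
418	0.4641
1890	-0.7521
141	-2.9214
750	0.2313
107	-1.0972
741	-2.4728
64	-0.3759
152	-1.178
229	-4.735
190	-2.1182
101	-3.4058
275	0.2075
1561	-1.7016
429	-2.2008
57	-2.4057
534	-2.282
86	-2.4693
120	-2.6733
365	-2.589
99	-2.0805
135	-3.8226
17	-3.7437
81	-3.6651
884	-1.0496
40	-1.6553
28	-0.1142
200	-0.2756
94	-4.1547
296	-2.6026
600	-2.2954
1293	-2.3843
180	-2.0196
169	-3.9914
911	-1.9555
124	0.2668
118	-2.1901
139	-1.6415
171	-1.5742
749	-3.2763
65	-3.5269
222	-2.6401
182	-1.9953
154	0.3161
272	-1.5282
598	-3.1994
330	-2.8055
80	-0.1589
630	-3.0464
359	-1.0805
714	0.3453
224	-2.8752
238	-2.62
197	-2.082
166	-1.2115
598	-1.2738
531	-2.2657
291	-1.9209
502	-2.5973
3154	-2.2733
309	0.0718
655	-2.0758
752	-0.1104
124	0.1582
630	-2.4145
502	-1.825
278	-1.1174
69	-2.6799
98	-2.9379
119	-0.3037
228	-2.0665
330	0.3155
112	-1.6669
841	-3.3981
210	-0.2663
417	-2.1972
208	-3.2159
114	-3.3895
267	-1.8354
202	-1e-04
171	-0.9726
980	-2.7802
777	-2.0068
101	-2.7367
81	-2.5525
81	-2.8409
223	-2.9377
2200	-0.3121
618	0.5035
180	-4.0162
303	-3.1821
176	-1.5103
341	-2.2526
418	-5.0333
213	-1.5105
24	-3.2623
339	-3.8593
971	-2.6058
74	-1.2821
257	-0.6576
246	-2.2142
642	-3.4576
262	-2.8852
520	-3.0891
674	-4.3786
90	0.3991
1270	-0.6861
552	-2.8307
724	-0.3475
241	-3.2543
270	-1.2076
389	-1.7788
196	0.7387
1154	-0.2327
250	-1.9752
409	-1.9054
561	-2.0341
372	-2.0201
81	-1.9319
159	-1.1661
156	-1.9048
441	-1.9471
480	-1.1151
198	-1.5175
1787	-1.0018
318	-2.1187
395	0.0168
229	-3.4555
190	0.4971
37	-3.8979
263	-4.6197
175	-0.6225
1297	-1.7316
1346	-2.463
388	-3.194
72	-1.2479
715	-1.6043
62	-1.2742
409	-1.3314
1618	0.5775
119	-3.8172
307	-3.3241
253	-2.5476
305	-2.8246
660	0.011
845	-2.3947
432	0.4326
181	-0.4904
266	-0.9152
274	-3.6218
107	-1.4547
195	-3.3927
780	-2.103
168	-4.3009
68	-2.9573
243	-2.652
501	-0.499
1769	-0.2459
332	-2.7896
185	-0.5127
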