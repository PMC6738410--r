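# MethylTL 0.2.0 clock coefficients (kb per unit beta)
# alpha: 0.5
# lambda: 0.02
# lambda_rule: 1se
probe_id	weight
(Intercept)	9
cg00346501	-1.956
cg00576892	-1.2075
cg00960820	-0.7388
cg01271412	-3.2009
cg01287195	-1.477
cg01426706	1.2744
cg01571723	3.0236
cg02901458	0.6162
cg03871414	-0.5261
cg04107634	1.1958
cg04258665	-0.7104
cg04922682	-0.4396
cg05393469	0.5922
cg05436953	0.2501
cg05751654	-0.8733
cg06015840	1.9022
cg06022436	1.5276
cg06390583	-0.4847
cg07119419	-2.366
cg07437774	2.2588
cg07513924	3.0529
cg07723644	-2.4061
cg07894566	-1.2899
cg08249741	0.0671
cg08579030	3.0869
cg08861032	1.2727
cg09256214	0.0919
cg09476945	0.4407
cg09879914	-1.1839
cg09889803	2.8161
cg09956316	-1.5863
cg10200808	2.8919
cg10445153	-1.1587
cg11303253	-1.2663
cg11437586	2.7725
cg11712273	1.5425
cg11843543	-2.7733
cg12494546	-1.2179
cg12714087	1.5174
cg13260360	-2.7599
cg13635986	1.8702
cg13683934	-1.4857
cg13693784	-1.0715
cg13758038	-0.5042
cg13874122	-0.7614
cg13892348	1.5548
cg13994347	-3.3746
cg14104740	0.4497
cg14377076	1.9733
cg14409746	-0.7429
cg14483286	0.148
cg15034368	2.3939
cg15373043	0.9308
cg15936731	1.7325
cg15965978	-2.3347
cg16128089	-2.6481
cg16556970	2.3461
cg16622235	1.5033
cg16774958	-0.5847
cg17142360	-0.0655
cg17415457	-1.2564
cg17529002	-2.9204
cg18044869	1.6076
cg18255870	-1.0632
cg18544457	-2.6645
cg18833245	-1.9826
cg18989277	3.3128
cg19886464	-1.2156
cg20642438	-1.0909
cg20696803	3.1658
cg21878297	-3.2635
cg22251119	-2.8656
cg22306767	3.0837
cg22435008	-1.0295
cg22639014	1.0959
cg22779580	1.8222
cg23154903	1.9278
cg23439009	-2.4562
cg23700416	-1.2287
cg23806216	1.6511
cg23959930	-1.4785
cg24345142	1.109
cg24725353	3.3159
cg25280932	-2.004
cg25512726	-1.369
cg25911130	1.0168
cg26088014	-3.2602
cg26708939	1.5445
cg26724898	-1.0812
cg27078745	-2.9783
cg27742121	-0.7091
cg27918685	3.4415
cg28589673	-0.8152
cg28703045	1.7346
cg29021812	1.1605
cg29670420	-1.8763
cg29928339	2.1859
cg30061443	-2.2411
cg30240032	2.1591
cg30593574	-0.8163
cg31191759	-1.6385
cg31349518	1.1789
cg31740650	3.1715
cg34073944	2.8881
cg34312876	3.4705
cg34662208	0.152
cg34687001	-3.4644
cg34799110	-2.5113
cg35045799	2.0265
cg35087827	-0.0904
cg35182946	3.0904
cg36781568	-3.3623
cg37013146	-3.0395
cg37761653	-3.0746
cg37926052	2.3376
cg38311061	-0.8088
cg38576487	-1.2138
cg38657659	-1.2181
cg40238151	2.503
cg41618142	-0.7355
cg41915152	-1.924
cg42698152	2.8707
cg43041351	-2.1684
cg43713575	2.7746
cg43930974	0.8299
cg44261085	-1.7803
cg44875844	2.1691
cg44998478	2.094
cg45081912	2.9779
cg45197406	3.1461
cg45566816	-1.5403
cg45654917	2.9653
cg46680417	3.1538
cg47089156	-3.2313
cg47630706	2.3459
cg48160108	1.5408
cg48724207	-3.1323
cg48806852	-1.6261
cg48950241	-1.4958
cg49157548	0.8311
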