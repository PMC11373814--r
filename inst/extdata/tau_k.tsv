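# K-shell photoionization cross section tau_K (cm^2/g)
# Cromer-Liberman photoabsorption (gemmi 0.7.4) minus the power-law
#   extrapolation of the sub-edge (L+M shell) contribution.
# Log-log linear interpolation between grid points. Generated 2026-10-01.
element	energy_keV	tau_cm2_g
Cl	2.8234	1553.7
Cl	2.8244	1552.47
Cl	2.9918	1349.34
Cl	3.16911	1164.5
Cl	3.35694	1004.19
Cl	3.5559	865.138
Cl	3.76665	744.779
Cl	3.98989	640.617
Cl	4.22636	550.447
Cl	4.47684	472.474
Cl	4.74217	405.122
Cl	5.02323	347.004
Cl	5.32095	296.894
Cl	5.63631	253.751
Cl	5.97036	216.49
Cl	6.3242	184.542
Cl	6.69902	157.176
Cl	7.09606	133.755
Cl	7.51663	113.727
Cl	7.96212	96.6158
Cl	8.43401	82.0086
Cl	8.93388	69.5468
Cl	9.46337	58.8957
Cl	10.0242	49.8426
Cl	10.6184	42.1526
Cl	11.2477	35.625
Cl	11.9143	30.0876
Cl	12.6204	25.3793
Cl	13.3684	21.3855
Cl	14.1607	18.0104
Cl	15	15.1597
K	3.6084	1086.99
K	3.6094	1086.19
K	3.79112	953.921
K	3.982	841.642
K	4.18248	742.007
K	4.39306	653.664
K	4.61424	575.395
K	4.84655	506.124
K	5.09056	444.852
K	5.34686	390.691
K	5.61606	342.851
K	5.89881	300.628
K	6.19581	263.399
K	6.50775	230.6
K	6.8354	201.726
K	7.17954	176.327
K	7.54101	153.967
K	7.92068	134.353
K	8.31947	117.164
K	8.73833	102.11
K	9.17829	88.8877
K	9.64039	77.3132
K	10.1258	67.2123
K	10.6356	58.4017
K	11.171	50.7204
K	11.7335	44.0271
K	12.3242	38.1975
K	12.9447	33.1229
K	13.5964	28.7076
K	14.281	24.8679
K	15	21.5306
P	2.1465	2369.27
P	2.1475	2367.09
P	2.29637	2039.71
P	2.45556	1715.13
P	2.62579	1441.95
P	2.80782	1212.18
P	3.00246	1018.72
P	3.2106	854.466
P	3.43317	715.716
P	3.67117	598.64
P	3.92566	500.002
P	4.1978	417.045
P	4.48881	347.037
P	4.79999	288.313
P	5.13274	239.261
P	5.48855	198.334
P	5.86904	164.225
P	6.27589	135.829
P	6.71096	112.216
P	7.17618	92.6024
P	7.67366	76.3302
P	8.20562	62.8454
P	8.77445	51.6833
P	9.38272	42.4383
P	10.0332	34.7737
P	10.7287	28.4732
P	11.4724	23.2975
P	12.2677	19.0489
P	13.1182	15.5637
P	14.0276	12.7067
P	15	10.3665
S	2.473	1975.42
S	2.474	1973.67
S	2.63262	1705.87
S	2.80142	1452.55
S	2.98104	1237.23
S	3.17218	1054.25
S	3.37556	897.022
S	3.592	762.275
S	3.8223	646.99
S	4.06738	548.479
S	4.32817	464.401
S	4.60568	392.706
S	4.90098	331.679
S	5.21521	279.535
S	5.5496	235.322
S	5.90542	197.911
S	6.28406	166.286
S	6.68697	139.578
S	7.11572	117.046
S	7.57196	98.0542
S	8.05745	82.063
S	8.57407	68.6115
S	9.12381	57.2964
S	9.7088	47.793
S	10.3313	39.8351
S	10.9937	33.1609
S	11.6986	27.5684
S	12.4487	22.9044
S	13.2468	19.0172
S	14.0962	15.7795
S	15	13.0845
Si	1.8399	3057.44
Si	1.8409	3054.72
Si	1.979	2631
Si	2.12746	2182.34
Si	2.28706	1809.41
Si	2.45863	1500.74
Si	2.64308	1244.46
Si	2.84136	1029.95
Si	3.05451	850.633
Si	3.28365	701.018
Si	3.52999	576.82
Si	3.7948	473.551
Si	4.07948	387.891
Si	4.38552	317.324
Si	4.71451	259.266
Si	5.06819	211.559
Si	5.4484	172.409
Si	5.85713	140.322
Si	6.29652	114.058
Si	6.76887	92.5899
Si	7.27666	75.0636
Si	7.82255	60.7745
Si	8.40938	49.1358
Si	9.04024	39.6622
Si	9.71842	31.93
Si	10.4475	25.6855
Si	11.2312	20.6461
Si	12.0738	16.5823
Si	12.9795	13.3078
Si	13.9533	10.6712
Si	15	8.55002
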