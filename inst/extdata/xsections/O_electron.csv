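energy_keV,stopping_MeVcm2g
0.25,219.981
0.267965057,212.981
0.287221088,206.047
0.307860861,199.192
0.329983812,192.423
0.353696525,185.752
0.379113238,179.185
0.406356402,172.732
0.435557266,166.398
0.466856511,160.191
0.500404926,154.115
0.536364139,148.177
0.574907389,142.379
0.616220365,136.726
0.660502101,131.22
0.707965934,125.864
0.758840527,120.659
0.813370981,115.606
0.871820006,110.707
0.934469191,105.96
1.00162036,101.367
1.07359703,96.9246
1.15074596,92.6333
1.23343883,88.4911
1.32207402,84.4963
1.41707856,80.6465
1.51891015,76.9396
1.62805938,73.3728
1.7450521,69.9432
1.87045195,66.6481
2.00486305,63.4841
2.14893297,60.448
2.30335578,57.5366
2.46887546,54.7464
2.64628941,52.0739
2.83645238,49.5156
3.04028049,47.0679
3.25875574,44.7273
3.49293068,42.4903
3.74393348,40.3533
4.01297339,38.3128
4.30134658,36.3655
4.61044233,34.5077
4.94174977,32.7363
5.29686504,31.0478
5.67749897,29.4391
6.08548534,27.907
6.52278971,26.4483
6.99151887,25.0602
7.49393102,23.7396
8.03244662,22.4836
8.60966007,21.2896
9.22835221,20.1548
9.89150371,19.0767
10.6023094,18.0526
11.3641938,17.0803
12.1808274,16.1573
13.0561444,15.2814
13.9943619,14.4503
15,13.6621
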