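energy_keV,stopping_MeVcm2g
0.25,90.5269
0.267965057,88.9344
0.287221088,87.2995
0.307860861,85.6249
0.329983812,83.9135
0.353696525,82.1685
0.379113238,80.3932
0.406356402,78.5909
0.435557266,76.7651
0.466856511,74.9195
0.500404926,73.0575
0.536364139,71.1829
0.574907389,69.2992
0.616220365,67.4103
0.660502101,65.5196
0.707965934,63.6306
0.758840527,61.7469
0.813370981,59.8718
0.871820006,58.0086
0.934469191,56.1602
1.00162036,54.3297
1.07359703,52.5199
1.15074596,50.7332
1.23343883,48.9723
1.32207402,47.2392
1.41707856,45.5361
1.51891015,43.8647
1.62805938,42.2268
1.7450521,40.6239
1.87045195,39.0571
2.00486305,37.5276
2.14893297,36.0364
2.30335578,34.5841
2.46887546,33.1714
2.64628941,31.7987
2.83645238,30.4662
3.04028049,29.1742
3.25875574,27.9225
3.49293068,26.7112
3.74393348,25.54
4.01297339,24.4086
4.30134658,23.3166
4.61044233,22.2634
4.94174977,21.2485
5.29686504,20.2714
5.67749897,19.3312
6.08548534,18.4272
6.52278971,17.5587
6.99151887,16.7248
7.49393102,15.9246
8.03244662,15.1573
8.60966007,14.422
9.22835221,13.7177
9.89150371,13.0435
10.6023094,12.3985
11.3641938,11.7818
12.1808274,11.1923
13.0561444,10.6293
13.9943619,10.0916
15,9.57853
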