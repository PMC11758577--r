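energy_keV,stopping_MeVcm2g
0.25,154.075
0.267965057,150.208
0.287221088,146.317
0.307860861,142.409
0.329983812,138.493
0.353696525,134.575
0.379113238,130.663
0.406356402,126.764
0.435557266,122.886
0.466856511,119.033
0.500404926,115.214
0.536364139,111.433
0.574907389,107.696
0.616220365,104.01
0.660502101,100.378
0.707965934,96.8051
0.758840527,93.2955
0.813370981,89.8529
0.871820006,86.4806
0.934469191,83.1816
1.00162036,79.9582
1.07359703,76.8128
1.15074596,73.7472
1.23343883,70.7626
1.32207402,67.8604
1.41707856,65.0412
1.51891015,62.3056
1.62805938,59.6538
1.7450521,57.0857
1.87045195,54.6011
2.00486305,52.1993
2.14893297,49.8798
2.30335578,47.6416
2.46887546,45.4836
2.64628941,43.4046
2.83645238,41.4032
3.04028049,39.478
3.25875574,37.6274
3.49293068,35.8498
3.74393348,34.1433
4.01297339,32.5062
4.30134658,30.9366
4.61044233,29.4327
4.94174977,27.9925
5.29686504,26.6142
5.67749897,25.2957
6.08548534,24.0352
6.52278971,22.8306
6.99151887,21.6801
7.49393102,20.5818
8.03244662,19.5337
8.60966007,18.534
9.22835221,17.5809
9.89150371,16.6726
10.6023094,15.8074
11.3641938,14.9834
12.1808274,14.1991
13.0561444,13.4527
13.9943619,12.7428
15,12.0677
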