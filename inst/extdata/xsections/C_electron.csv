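energy_keV,stopping_MeVcm2g
0.25,243.686
0.267965057,235.433
0.287221088,227.296
0.307860861,219.285
0.329983812,211.41
0.353696525,203.68
0.379113238,196.102
0.406356402,188.684
0.435557266,181.431
0.466856511,174.349
0.500404926,167.442
0.536364139,160.715
0.574907389,154.168
0.616220365,147.806
0.660502101,141.629
0.707965934,135.638
0.758840527,129.833
0.813370981,124.214
0.871820006,118.78
0.934469191,113.529
1.00162036,108.46
1.07359703,103.571
1.15074596,98.8594
1.23343883,94.3215
1.32207402,89.9547
1.41707856,85.7555
1.51891015,81.7204
1.62805938,77.8455
1.7450521,74.1269
1.87045195,70.5606
2.00486305,67.1425
2.14893297,63.8682
2.30335578,60.7336
2.46887546,57.7343
2.64628941,54.8659
2.83645238,52.1243
3.04028049,49.5051
3.25875574,47.004
3.49293068,44.6168
3.74393348,42.3393
4.01297339,40.1675
4.30134658,38.0973
4.61044233,36.1247
4.94174977,34.246
5.29686504,32.4572
5.67749897,30.7548
6.08548534,29.1351
6.52278971,27.5947
6.99151887,26.1301
7.49393102,24.7381
8.03244662,23.4155
8.60966007,22.1592
9.22835221,20.9663
9.89150371,19.8339
10.6023094,18.7592
11.3641938,17.7396
12.1808274,16.7724
13.0561444,15.8553
13.9943619,14.9858
15,14.1617
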