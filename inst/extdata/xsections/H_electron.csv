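energy_keV,stopping_MeVcm2g
0.25,867.041
0.267965057,827.884
0.287221088,790.151
0.307860861,753.818
0.329983812,718.86
0.353696525,685.249
0.379113238,652.955
0.406356402,621.947
0.435557266,592.195
0.466856511,563.664
0.500404926,536.322
0.536364139,510.134
0.574907389,485.065
0.616220365,461.081
0.660502101,438.147
0.707965934,416.228
0.758840527,395.29
0.813370981,375.298
0.871820006,356.218
0.934469191,338.017
1.00162036,320.661
1.07359703,304.119
1.15074596,288.358
1.23343883,273.348
1.32207402,259.059
1.41707856,245.459
1.51891015,232.522
1.62805938,220.219
1.7450521,208.522
1.87045195,197.405
2.00486305,186.844
2.14893297,176.813
2.30335578,167.288
2.46887546,158.247
2.64628941,149.667
2.83645238,141.527
3.04028049,133.806
3.25875574,126.485
3.49293068,119.545
3.74393348,112.968
4.01297339,106.735
4.30134658,100.831
4.61044233,95.2387
4.94174977,89.9435
5.29686504,84.9305
5.67749897,80.1856
6.08548534,75.6954
6.52278971,71.4469
6.99151887,67.4281
7.49393102,63.6271
8.03244662,60.0327
8.60966007,56.6345
9.22835221,53.4221
9.89150371,50.386
10.6023094,47.5169
11.3641938,44.8061
12.1808274,42.2452
13.0561444,39.8264
13.9943619,37.5421
15,35.385
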