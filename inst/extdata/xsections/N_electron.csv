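energy_keV,stopping_MeVcm2g
0.25,237.617
0.267965057,229.691
0.287221088,221.867
0.307860861,214.156
0.329983812,206.568
0.353696525,199.112
0.379113238,191.795
0.406356402,184.626
0.435557266,177.61
0.466856511,170.754
0.500404926,164.06
0.536364139,157.535
0.574907389,151.181
0.616220365,145
0.660502101,138.995
0.707965934,133.166
0.758840527,127.514
0.813370981,122.039
0.871820006,116.741
0.934469191,111.619
1.00162036,106.671
1.07359703,101.896
1.15074596,97.2907
1.23343883,92.8533
1.32207402,88.5808
1.41707856,84.4701
1.51891015,80.5181
1.62805938,76.7211
1.7450521,73.0757
1.87045195,69.5779
2.00486305,66.224
2.14893297,63.0098
2.30335578,59.9315
2.46887546,56.9849
2.64628941,54.166
2.83645238,51.4705
3.04028049,48.8945
3.25875574,46.4338
3.49293068,44.0844
3.74393348,41.8423
4.01297339,39.7035
4.30134658,37.6641
4.61044233,35.7204
4.94174977,33.8686
5.29686504,32.105
5.67749897,30.4261
6.08548534,28.8284
6.52278971,27.3085
6.99151887,25.863
7.49393102,24.4889
8.03244662,23.183
8.60966007,21.9424
9.22835221,20.764
9.89150371,19.6452
10.6023094,18.5832
11.3641938,17.5753
12.1808274,16.6192
13.0561444,15.7124
13.9943619,14.8525
15,14.0374
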