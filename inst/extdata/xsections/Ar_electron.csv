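energy_keV,stopping_MeVcm2g
0.25,131.977
0.267965057,128.792
0.287221088,125.58
0.307860861,122.347
0.329983812,119.099
0.353696525,115.842
0.379113238,112.583
0.406356402,109.328
0.435557266,106.083
0.466856511,102.853
0.500404926,99.6434
0.536364139,96.4605
0.574907389,93.3089
0.616220365,90.1934
0.660502101,87.1184
0.707965934,84.088
0.758840527,81.1062
0.813370981,78.1763
0.871820006,75.3015
0.934469191,72.4847
1.00162036,69.7283
1.07359703,67.0345
1.15074596,64.4053
1.23343883,61.842
1.32207402,59.3461
1.41707856,56.9184
1.51891015,54.5597
1.62805938,52.2705
1.7450521,50.0509
1.87045195,47.901
2.00486305,45.8206
2.14893297,43.8092
2.30335578,41.8664
2.46887546,39.9913
2.64628941,38.1832
2.83645238,36.441
3.04028049,34.7635
3.25875574,33.1497
3.49293068,31.5982
3.74393348,30.1077
4.01297339,28.6766
4.30134658,27.3036
4.61044233,25.987
4.94174977,24.7254
5.29686504,23.5171
5.67749897,22.3606
6.08548534,21.2541
6.52278971,20.1962
6.99151887,19.1852
7.49393102,18.2194
8.03244662,17.2974
8.60966007,16.4174
9.22835221,15.578
9.89150371,14.7777
10.6023094,14.0149
11.3641938,13.2882
12.1808274,12.5962
13.0561444,11.9373
13.9943619,11.3104
15,10.714
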