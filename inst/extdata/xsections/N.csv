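# element=N Z=7 mass=14.007 k_edge_keV=0.41 l_edge_keV=0.009 kalpha_keV=0.392 omega_k=0.0052
energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g
0.25,7398.94,0.0118527,1.0511
0.3,4691.34,0.0140539,1.0511
0.35,3191.4,0.0162032,1.0511
0.4,2285.75,0.0183025,1.0511
0.41,2148.93,0.0187164,1.0511
0.41,42998.9,0.0187164,1.0511
0.45,32899.9,0.0203533,1.0511
0.5,24300,0.0223574,1.0511
0.6,14384.4,0.0262314,1.0511
0.7,9233.29,0.0299361,1.0511
0.8,6288.78,0.0334822,1.0511
0.9,4481.65,0.0368794,1.0511
1,3309.91,0.0401368,1.0511
1.1,2537.79,0.0432626,1.0511
1.25,1777.08,0.0477211,1.0511
1.4,1295.65,0.0519241,1.0511
1.5,1068.89,0.0545945,1.0511
1.75,693.696,0.0608501,1.0511
2,476.882,0.0665657,1.0511
2.25,337.299,0.0718065,1.0511
2.5,247.361,0.0766275,1.0511
2.75,186.778,0.0810758,1.0511
3,144.464,0.0851914,1.0511
3.3,108.733,0.0897394,1.0511
3.5,91.2009,0.0925584,1.0511
4,61.0961,0.0989543,1.0511
4.5,42.8001,0.104551,1.0511
5,31.1585,0.109484,0.931973
5.5,23.1783,0.113857,0.777602
6,17.6772,0.117755,0.659112
6.6,13.1227,0.121901,0.549937
7,10.9099,0.124387,0.491768
7.5,8.77818,0.127223,0.43135
8,7.15546,0.129793,0.381571
8.5,5.89907,0.132129,0.340056
9,4.91164,0.134259,0.30506
9.5,4.12518,0.136204,0.275278
10,3.4913,0.137986,0.249716
11,2.61735,0.141126,0.208353
12,2.00236,0.143789,0.176605
13,1.55675,0.146061,0.151689
14,1.22579,0.148008,0.131766
15,0.97474,0.149683,0.115577
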