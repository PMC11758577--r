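# element=C Z=6 mass=12.011 k_edge_keV=0.284 l_edge_keV=0.007 kalpha_keV=0.277 omega_k=0.0028
energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g
0.25,2000,0.0127366,0.90057
0.284,1600,0.0143426,0.90057
0.284,40000,0.0143426,0.90057
0.3,35254.5,0.0150887,0.90057
0.35,24714.9,0.0173813,0.90057
0.4,18169.2,0.0196168,0.90057
0.45,13850.8,0.0217971,0.90057
0.5,10865.3,0.0239242,0.90057
0.6,7138.32,0.0280264,0.90057
0.7,5004.26,0.0319375,0.90057
0.8,3678.9,0.0356704,0.90057
0.9,2804.5,0.0392366,0.90057
1,2200,0.0426469,0.90057
1.1,1644.8,0.0459112,0.90057
1.25,1113.53,0.0505531,0.90057
1.4,787.978,0.0549137,0.90057
1.5,638.383,0.0576766,0.90057
1.75,398.836,0.0641259,0.90057
2,265.358,0.0699901,0.90057
2.25,185.242,0.0753434,0.90057
2.5,134.311,0.0802478,0.90057
2.75,100.416,0.0847558,0.90057
3,77,0.088912,0.90057
3.3,57.5586,0.0934885,0.90057
3.5,48.0937,0.0963164,0.90057
4,31.9909,0.102708,0.90057
4.5,22.3279,0.108272,0.90057
5,16.1861,0.113152,0.754233
5.5,12.0993,0.117461,0.629302
6,9.2765,0.121288,0.53341
6.6,6.93432,0.125342,0.445056
7,5.79405,0.127764,0.397981
7.5,4.69352,0.130521,0.349086
8,3.85408,0.133011,0.3088
8.5,3.20282,0.135268,0.275203
9,2.68993,0.13732,0.246881
9.5,2.2806,0.13919,0.222779
10,1.95,0.140899,0.202092
11,1.4604,0.143897,0.168617
12,1.12162,0.146429,0.142924
13,0.879824,0.148578,0.12276
14,0.702694,0.150411,0.106636
15,0.57,0.151979,0.0935352
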