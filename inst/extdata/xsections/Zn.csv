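# element=Zn Z=30 mass=65.38 k_edge_keV=9.659 l_edge_keV=1.088 kalpha_keV=8.639 omega_k=0.474
energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g
0.25,30000,0.00542303,4.13611
0.3,25967.5,0.00646817,4.13611
0.35,22984,0.00750068,4.13611
0.4,20678.1,0.0085208,4.13611
0.45,18837,0.00952873,4.13611
0.5,17329.4,0.0105247,4.13611
0.6,15000,0.0124815,4.13611
0.7,12070,0.0143928,4.13611
0.8,9998.83,0.0162601,4.13611
0.9,8469.02,0.0180849,4.13611
1,7300,0.0198686,4.13611
1.1,6337.38,0.0216125,4.13611
1.25,5242.51,0.0241564,4.13611
1.4,4431.14,0.0266176,4.13611
1.5,4000,0.0282144,4.13611
1.75,3075.98,0.0320599,4.13611
2,2450,0.0357087,4.13611
2.25,1860.57,0.0391749,4.13611
2.5,1454.56,0.0424712,4.13611
2.75,1164.17,0.0456093,4.13611
3,950,0.0485998,4.13611
3.3,734.346,0.0520072,4.13611
3.5,626.421,0.054176,4.13611
4,436.718,0.0592678,4.13611
4.5,317.696,0.0639325,4.13611
5,239,0.0682188,4.13611
5.5,181.377,0.0721683,4.13611
6,140.994,0.0758167,4.13611
6.6,107,0.0798404,3.70773
7,90.1925,0.0823295,3.31555
7.5,73.8162,0.0852441,2.90821
8,61.2,0.0879591,2.57259
8.5,51.3643,0.0904926,2.29269
9,43.5433,0.0928606,2.05675
9.5,37.2444,0.0950771,1.85595
9.659,35.5,0.0957523,1.79833
9.659,263,0.0957523,1.79833
10,240,0.0971549,1.68361
11,185.084,0.100938,1.40474
12,146,0.104286,1.19069
13,117.662,0.107262,1.0227
14,96.3538,0.109916,0.888379
15,80,0.112291,0.779234
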