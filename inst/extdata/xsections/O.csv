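# element=O Z=8 mass=15.999 k_edge_keV=0.533 l_edge_keV=0.0135 kalpha_keV=0.525 omega_k=0.0083
energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g
0.25,18398.8,0.0111361,1.20194
0.3,11660.9,0.0132136,1.20194
0.35,7929.88,0.0152451,1.20194
0.4,5677.99,0.0172319,1.20194
0.45,4228.87,0.0191756,1.20194
0.5,3248.93,0.0210775,1.20194
0.533,2768.78,0.0223105,1.20194
0.533,22168.8,0.0223105,1.20194
0.6,16398.8,0.024761,1.20194
0.7,11166.3,0.0282924,1.20194
0.8,8004.35,0.0316806,1.20194
0.9,5967.44,0.034934,1.20194
1,4588.76,0.0380604,1.20194
1.1,3554.4,0.0410668,1.20194
1.25,2523.3,0.045366,1.20194
1.4,1862.23,0.0494304,1.20194
1.5,1547.75,0.0520187,1.20194
1.75,1006.86,0.0581004,1.20194
2,693.634,0.0636797,1.20194
2.25,494.35,0.0688147,1.20194
2.5,365.041,0.0735548,1.20194
2.75,277.388,0.0779426,1.20194
3,215.816,0.0820144,1.20194
3.3,162.767,0.0865279,1.20194
3.5,136.708,0.089333,1.20194
4,91.9023,0.0957186,1.20194
4.5,64.2854,0.101332,1.20194
5,46.674,0.106298,1.11969
5.5,34.9295,0.110717,0.934223
6,26.7935,0.114669,0.791867
6.6,19.9988,0.118887,0.660703
7,16.6867,0.121424,0.590817
7.5,13.4872,0.124324,0.518231
8,11.0446,0.12696,0.458425
8.5,9.15696,0.129361,0.408548
9,7.66821,0.131555,0.366504
9.5,6.47852,0.133564,0.330723
10,5.51658,0.135408,0.300013
11,4.12536,0.138667,0.250319
12,3.15375,0.141443,0.212175
13,2.45459,0.143821,0.182241
14,1.93861,0.145867,0.158306
15,1.54951,0.147634,0.138856
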