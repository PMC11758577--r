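# element=Si Z=14 mass=28.085 k_edge_keV=1.839 l_edge_keV=0.116 kalpha_keV=1.74 omega_k=0.05
energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g
0.25,43997.9,0.00850761,2.09689
0.3,28880.3,0.0101208,2.09689
0.35,20231,0.0117063,2.09689
0.4,14862.9,0.0132648,2.09689
0.45,11323.5,0.0147969,2.09689
0.5,8877.89,0.0163034,2.09689
0.6,5627.46,0.0192416,2.09689
0.7,3827.21,0.0220843,2.09689
0.8,2740.43,0.024836,2.09689
0.9,2040.95,0.0275007,2.09689
1,1567.87,0.0300826,2.09689
1.1,1217.12,0.0325852,2.09689
1.25,866.455,0.0361981,2.09689
1.4,640.917,0.0396516,2.09689
1.5,533.361,0.0418703,2.09689
1.75,351.982,0.0471443,2.09689
1.839,307.854,0.0489334,2.09689
1.839,3469.85,0.0489334,2.09689
2,2774.85,0.0520594,2.09689
2.25,2048.85,0.0566499,2.09689
2.5,1561.85,0.0609458,2.09689
2.75,1221.73,0.0649736,2.09689
3,976.234,0.0687567,2.09689
3.3,753.472,0.0730024,2.09689
3.5,642.068,0.0756694,2.09689
4,446.415,0.0818245,2.09689
4.5,323.801,0.0873345,2.09689
5,242.811,0.0922909,2.09689
5.5,184.553,0.0967687,2.00479
6,143.811,0.10083,1.6993
6.6,109.411,0.105226,1.41783
7,92.4104,0.107902,1.26786
7.5,75.8013,0.110993,1.11209
8,62.97,0.113831,0.983755
8.5,52.8957,0.116443,0.876722
9,44.8726,0.118854,0.786497
9.5,38.4016,0.121082,0.709714
10,33.123,0.123146,0.643811
11,24.974,0.12684,0.53717
12,19.287,0.130039,0.455317
13,15.1969,0.132824,0.39108
14,12.1795,0.13526,0.339715
15,9.90462,0.137397,0.297978
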