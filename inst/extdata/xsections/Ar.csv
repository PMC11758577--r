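# element=Ar Z=18 mass=39.948 k_edge_keV=3.206 l_edge_keV=0.27 kalpha_keV=2.958 omega_k=0.118
energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g
0.25,34997.6,0.00681635,2.43694
0.3,25811.1,0.00811666,2.43694
0.35,19952.7,0.00939708,2.43694
0.4,15964.4,0.0106581,2.43694
0.45,13113.5,0.0119,2.43694
0.5,10997.5,0.0131233,2.43694
0.6,7934,0.0155158,2.43694
0.7,6019.87,0.0178386,2.43694
0.8,4739.26,0.0200946,2.43694
0.9,3837.72,0.0222865,2.43694
1,3177.54,0.024417,2.43694
1.1,2457.14,0.0264885,2.43694
1.25,1740.27,0.0294904,2.43694
1.4,1281.57,0.0323723,2.43694
1.5,1063.68,0.0342303,2.43694
1.75,701.217,0.0386674,2.43694
2,488.52,0.042829,2.43694
2.25,354.575,0.046739,2.43694
2.5,266.04,0.0504189,2.43694
2.75,205.021,0.0538876,2.43694
3,161.506,0.057162,2.43694
3.206,128.503,0.059725,2.43694
3.206,1307.5,0.059725,2.43694
3.3,1210.05,0.0608562,2.43694
3.5,1033.45,0.0631873,2.43694
4,722.281,0.0685989,2.43694
4.5,526.392,0.0734817,2.43694
5,396.485,0.0779059,2.43694
5.5,306.361,0.0819295,2.43694
6,242.252,0.0856014,2.16732
6.6,187.382,0.0896009,1.80832
7,159.9,0.0920486,1.61705
7.5,132.758,0.0948889,1.41838
8,111.549,0.0975095,1.2547
8.5,94.7166,0.0999328,1.11819
9,81.1755,0.102178,1.00311
9.5,70.1491,0.104262,0.90518
10,61.0727,0.1062,0.821126
11,46.5016,0.109689,0.685115
12,36.2469,0.112733,0.580718
13,28.8144,0.115401,0.49879
14,23.2918,0.11775,0.433278
15,19.1001,0.119826,0.380046
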