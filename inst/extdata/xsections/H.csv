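# element=H Z=1 mass=1.008 k_edge_keV=0.0136 l_edge_keV=0.004 kalpha_keV=0.01 omega_k=0
energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g
0.25,560,0.0567201,0.298081
0.3,307.026,0.0661606,0.298081
0.35,184.711,0.0750865,0.298081
0.4,118.94,0.0835386,0.298081
0.45,80.6695,0.0915533,0.298081
0.5,57,0.0991634,0.298081
0.6,32.5835,0.113285,0.298081
0.7,20.3071,0.12611,0.298081
0.8,13.4824,0.137805,0.298081
0.9,9.39428,0.148513,0.298081
1,6.8,0.158353,0.298081
1.1,5.04892,0.167423,0.298081
1.25,3.38659,0.179772,0.298081
1.4,2.37688,0.190819,0.298081
1.5,1.91603,0.197557,0.298081
1.75,1.18375,0.212548,0.298081
2,0.78,0.225343,0.298081
2.25,0.535195,0.236382,0.298081
2.5,0.382105,0.245993,0.298081
2.75,0.281716,0.254431,0.298081
3,0.213288,0.261889,0.298081
3.3,0.157251,0.269762,0.283317
3.5,0.130279,0.274456,0.253349
4,0.085,0.284605,0.196578
4.5,0.0561983,0.29294,0.157161
5,0.0388132,0.299881,0.128649
5.5,0.0277696,0.305727,0.107339
6,0.020456,0.310698,0.0909832
6.6,0.0146356,0.315738,0.0759128
7,0.0119026,0.318636,0.0678832
7.5,0.00934074,0.321827,0.0595432
8,0.00744592,0.324608,0.0526717
8.5,0.00601764,0.327043,0.046941
9,0.00492291,0.32918,0.0421102
9.5,0.00407131,0.331061,0.0379991
10,0.0034,0.33272,0.0344706
11,0.00252569,0.335479,0.0287609
12,0.0019254,0.337634,0.0243783
13,0.00150004,0.339312,0.020939
14,0.00119048,0.340608,0.0181889
15,0.00096,0.341594,0.0159542
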