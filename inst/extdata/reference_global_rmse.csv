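patient,femur,tibia
1,0.57,0.74
2,0.97,0.94
3,0.82,0.81
4,0.77,1.03
5,0.90,0.97
6,1.04,0.79
7,0.72,0.70
8,1.21,0.98
9,1.03,1.09
10,1.57,1.09
11,1.41,0.90
12,0.75,0.84
13,0.85,0.93
14,0.87,0.88
15,0.97,0.99
16,0.72,0.86
17,0.74,0.69
18,0.87,0.62
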