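item,p_real,p_syn,abs_diff,relative_pct
1,0.704,0.679,0.025,3.589
2,0.661,0.653,0.008,1.212
3,0.376,0.371,0.005,1.310
4,0.453,0.445,0.007,1.634
5,0.750,0.707,0.043,5.793
6,0.704,0.699,0.004,0.613
7,0.535,0.515,0.020,3.802
8,0.652,0.613,0.040,6.096
9,0.248,0.226,0.022,8.933
10,0.523,0.504,0.019,3.599
11,0.470,0.444,0.027,5.701
12,0.531,0.501,0.031,5.742
13,0.811,0.832,0.021,2.585
14,0.512,0.487,0.024,4.759
15,0.795,0.798,0.003,0.427
16,0.628,0.619,0.009,1.473
17,0.572,0.561,0.011,1.941
18,0.805,0.823,0.018,2.260
19,0.702,0.656,0.045,6.459
20,0.800,0.801,0.000,0.039
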