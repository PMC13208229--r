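item,a_real,a_syn,se_a_asym,se_a_mc,b_real,b_syn,se_b_asym,se_b_mc
1,1.334,1.319,0.057,0.062,-0.866,-0.754,0.040,0.042
2,3.028,3.006,0.111,0.143,-0.481,-0.456,0.019,0.027
3,2.299,2.391,0.082,0.102,0.394,0.405,0.021,0.029
4,2.022,1.847,0.072,0.078,0.155,0.187,0.022,0.030
5,1.147,1.101,0.055,0.057,-1.200,-0.990,0.055,0.053
6,2.674,2.740,0.100,0.127,-0.639,-0.620,0.021,0.029
7,0.848,0.758,0.044,0.045,-0.192,-0.088,0.045,0.052
8,0.960,0.850,0.048,0.053,-0.780,-0.622,0.051,0.060
9,1.843,1.894,0.074,0.106,0.929,1.017,0.031,0.036
10,2.016,1.864,0.072,0.082,-0.074,-0.013,0.022,0.028
11,2.280,2.068,0.080,0.093,0.093,0.184,0.020,0.028
12,1.398,1.108,0.056,0.057,-0.123,-0.004,0.029,0.035
13,2.289,3.374,0.094,0.169,-1.109,-1.087,0.031,0.033
14,1.428,1.213,0.056,0.057,-0.045,0.054,0.029,0.038
15,1.958,2.417,0.081,0.112,-1.100,-1.032,0.034,0.038
16,1.653,1.595,0.063,0.069,-0.468,-0.441,0.028,0.036
17,2.283,2.157,0.081,0.104,-0.227,-0.196,0.021,0.028
18,2.947,4.266,0.121,0.234,-1.001,-1.005,0.024,0.032
19,1.301,1.236,0.056,0.056,-0.866,-0.678,0.041,0.042
20,1.582,1.697,0.069,0.090,-1.243,-1.202,0.044,0.045
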