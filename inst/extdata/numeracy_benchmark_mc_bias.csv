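item,a_real,a_mean_syn,a_diff,b_real,b_mean_syn,b_diff
1,1.334,1.384,0.050,-0.866,-0.736,0.130
2,3.028,3.075,0.047,-0.481,-0.464,0.017
3,2.299,2.307,0.008,0.394,0.376,-0.018
4,2.022,1.850,-0.172,0.155,0.160,0.005
5,1.147,1.163,0.016,-1.200,-0.971,0.229
6,2.674,2.767,0.093,-0.639,-0.622,0.017
7,0.848,0.747,-0.101,-0.192,-0.211,-0.019
8,0.960,0.869,-0.091,-0.780,-0.693,0.087
9,1.843,2.121,0.278,0.929,0.908,-0.021
10,2.016,1.940,-0.076,-0.074,-0.028,0.046
11,2.280,2.211,-0.069,0.093,0.151,0.058
12,1.398,1.289,-0.109,-0.123,-0.091,0.032
13,2.289,3.178,0.889,-1.109,-1.074,0.035
14,1.428,1.261,-0.167,-0.045,-0.008,0.037
15,1.958,2.374,0.416,-1.100,-1.089,0.011
16,1.653,1.545,-0.108,-0.468,-0.456,0.012
17,2.283,2.347,0.064,-0.227,-0.232,-0.005
18,2.947,4.022,1.075,-1.001,-1.001,0.000
19,1.301,1.213,-0.088,-0.866,-0.709,0.157
20,1.582,1.876,0.294,-1.243,-1.162,0.081
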