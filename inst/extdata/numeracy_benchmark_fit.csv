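item,infit_real,infit_syn,outfit_real,outfit_syn
1,0.976,0.972,0.875,0.895
2,0.885,0.893,0.635,0.635
3,0.874,0.855,0.763,0.720
4,0.911,0.908,0.820,0.877
5,0.970,0.971,0.946,0.953
6,0.911,0.929,0.716,0.636
7,0.978,0.979,0.951,0.963
8,0.972,0.975,0.960,0.969
9,0.870,0.860,0.879,0.848
10,0.924,0.925,0.800,0.830
11,0.898,0.905,0.774,0.771
12,0.959,0.964,0.881,0.928
13,0.923,0.904,0.856,0.466
14,0.955,0.959,0.880,0.915
15,0.960,0.966,0.776,0.659
16,0.942,0.950,0.909,0.902
17,0.917,0.912,0.763,0.821
18,0.891,0.831,0.733,0.413
19,0.976,0.974,0.887,0.906
20,0.962,0.974,0.892,0.815
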