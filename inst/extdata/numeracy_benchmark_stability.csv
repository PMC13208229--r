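seed,r_a,r_b,mad_marginal
101,0.929,0.996,0.019
202,0.943,0.995,0.014
303,0.954,0.996,0.015
404,0.951,0.996,0.014
505,0.943,0.992,0.017
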