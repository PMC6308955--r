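gender,t_lower,t_upper,d_rel
male,0.800,Inf,0.830
male,0.748,0.800,1.080
male,0.720,0.748,1.260
male,0.713,0.720,1.330
male,0.706,0.713,1.410
male,0.698,0.706,1.490
male,0.694,0.698,1.590
male,0.687,0.694,1.740
male,0.678,0.687,1.880
male,0.664,0.678,1.960
male,0.649,0.664,2.015
male,0.500,0.649,2.060
male,0.000,0.500,2.170
female,0.800,Inf,0.826
female,0.735,0.800,1.110
female,0.720,0.735,1.260
female,0.704,0.720,1.400
female,0.667,0.704,1.500
female,0.607,0.667,1.720
female,0.578,0.607,1.920
female,0.500,0.578,2.080
female,0.000,0.500,2.170
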