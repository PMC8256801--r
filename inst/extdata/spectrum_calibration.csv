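field,depth_cm,lateral_cm,family,mean_energy_keV,shape,low_energy_fraction,e_min_keV,e_max_keV
FF_6MV,3,0,gamma_exp,479.5713,1.6,0.04,1,1000
FF_6MV,3,6,gamma_exp,495.7427,1.6,0.112,1,1000
FF_6MV,3,8,gamma_exp,174.0162,1.6,0.136,1,1000
FF_6MV,3,10,gamma_exp,133.9541,1.6,0.16,1,1000
FF_6MV,5,0,gamma_exp,479.5713,1.6,0.04,1,1000
FF_6MV,5,6,gamma_exp,355.5621,1.6,0.112,1,1000
FF_6MV,5,8,gamma_exp,162.8297,1.6,0.136,1,1000
FF_6MV,5,10,gamma_exp,117.126,1.6,0.16,1,1000
FF_6MV,10,0,gamma_exp,479.5713,1.6,0.04,1,1000
FF_6MV,10,6,gamma_exp,355.5621,1.6,0.112,1,1000
FF_6MV,10,8,gamma_exp,133.642,1.6,0.136,1,1000
FF_6MV,10,10,gamma_exp,109.5367,1.6,0.16,1,1000
FFF_6MV,3,0,gamma_exp,466.584,1.6,0.05,1,1000
FFF_6MV,3,6,gamma_exp,484.0585,1.6,0.14,1,1000
FFF_6MV,3,8,gamma_exp,128.8949,1.6,0.17,1,1000
FFF_6MV,3,10,gamma_exp,70.13,1.6,0.2,1,1000
FFF_6MV,5,0,gamma_exp,466.584,1.6,0.05,1,1000
FFF_6MV,5,6,gamma_exp,268.58,1.6,0.14,1,1000
FFF_6MV,5,8,gamma_exp,98.3092,1.6,0.17,1,1000
FFF_6MV,5,10,gamma_exp,61.0239,1.6,0.2,1,1000
FFF_6MV,10,0,gamma_exp,466.584,1.6,0.05,1,1000
FFF_6MV,10,6,gamma_exp,249.3069,1.6,0.14,1,1000
FFF_6MV,10,8,gamma_exp,75.0479,1.6,0.17,1,1000
FFF_6MV,10,10,gamma_exp,49.5506,1.6,0.2,1,1000
REF_220KVP,NA,NA,gamma_exp,89.8424,1.6,0.1,1,220
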