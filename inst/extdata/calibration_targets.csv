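field,depth_cm,lateral_cm,y_dsb_target_1e11
FF_6MV,3,0,1.2255
FF_6MV,3,6,1.27
FF_6MV,3,8,1.41
FF_6MV,3,10,1.46
FF_6MV,5,0,1.2255
FF_6MV,5,6,1.3
FF_6MV,5,8,1.42
FF_6MV,5,10,1.48
FF_6MV,10,0,1.2255
FF_6MV,10,6,1.3
FF_6MV,10,8,1.45
FF_6MV,10,10,1.49
FFF_6MV,3,0,1.2345
FFF_6MV,3,6,1.29
FFF_6MV,3,8,1.47
FFF_6MV,3,10,1.57
FFF_6MV,5,0,1.2345
FFF_6MV,5,6,1.35
FFF_6MV,5,8,1.51
FFF_6MV,5,10,1.59
FFF_6MV,10,0,1.2345
FFF_6MV,10,6,1.36
FFF_6MV,10,8,1.55
FFF_6MV,10,10,1.62
REF_220KVP,NA,NA,1.51401869158878
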