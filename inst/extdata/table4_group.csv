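muscle,epoch,RMS,MDF,SAMPEN,CSD,RSD,LSD
TA,Pre-prep,0.589,0.836,0.653,0.033,0.566,0.447
TA,Pre-vol,0.759,0.723,0.362,0.050,0.919,0.114
TA,Auto-resp,0.396,0.339,0.621,0.195,0.098,0.933
TA,Stab,0.024,0.654,0.509,0.072,0.283,0.720
TA,Post-stab,0.050,0.446,0.672,0.017,0.206,0.184
GL,Pre-prep,0.782,0.273,0.266,0.444,0.271,0.746
GL,Pre-vol,0.212,0.890,0.173,0.519,0.127,0.497
GL,Auto-resp,0.661,0.020,0.160,0.519,0.983,0.924
GL,Stab,0.198,0.012,0.855,0.163,0.251,0.014
GL,Post-stab,0.612,0.565,0.049,0.194,0.007,0.728
GM,Pre-prep,0.005,0.532,0.077,0.113,0.598,0.458
GM,Pre-vol,0.147,0.587,0.022,0.045,0.002,0.544
GM,Auto-resp,0.524,0.767,0.065,0.842,0.464,0.722
GM,Stab,0.295,0.907,0.655,0.800,0.719,0.355
GM,Post-stab,0.037,0.979,0.002,0.005,0.002,0.233
SO,Pre-prep,0.133,0.888,0.517,0.022,0.257,0.093
SO,Pre-vol,0.026,0.986,0.084,0.760,0.900,0.077
SO,Auto-resp,0.105,0.468,0.085,0.459,0.078,0.887
SO,Stab,0.831,0.039,0.153,0.049,0.320,0.299
SO,Post-stab,0.000,0.923,0.000,0.015,0.000,0.003
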