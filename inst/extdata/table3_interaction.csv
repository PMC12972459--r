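muscle,epoch,RMS,MDF,SAMPEN,CSD,RSD,LSD
TA,Pre-prep,0.723,0.500,0.040,0.049,0.454,0.010
TA,Pre-vol,0.613,0.829,0.648,0.199,0.605,0.374
TA,Auto-resp,0.496,0.840,0.428,0.924,0.050,0.253
TA,Stab,0.465,0.677,0.479,0.768,0.566,0.787
TA,Post-stab,0.507,0.038,0.379,0.541,0.380,0.104
GL,Pre-prep,0.834,0.273,0.461,0.045,0.600,0.891
GL,Pre-vol,0.888,0.091,0.025,0.716,0.601,0.325
GL,Auto-resp,0.668,0.127,0.985,0.924,0.467,0.784
GL,Stab,0.933,0.294,0.438,0.105,0.439,0.381
GL,Post-stab,0.340,0.353,0.196,0.389,0.813,0.020
GM,Pre-prep,0.250,0.912,0.819,0.471,0.973,0.907
GM,Pre-vol,0.946,0.792,0.245,0.004,0.048,0.828
GM,Auto-resp,0.977,0.306,0.966,0.203,0.389,0.227
GM,Stab,0.551,0.736,0.295,0.963,0.835,0.631
GM,Post-stab,0.922,0.694,0.187,0.359,0.690,0.814
SO,Pre-prep,0.672,0.240,0.779,0.378,0.779,0.185
SO,Pre-vol,0.375,0.151,0.087,0.299,0.937,0.276
SO,Auto-resp,0.162,1.000,0.028,0.032,0.346,0.154
SO,Stab,0.513,0.032,0.266,0.884,0.595,0.601
SO,Post-stab,0.471,0.332,0.026,0.234,0.089,0.159
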