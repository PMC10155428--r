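muscle,L1,L2,L3,L4,L5,S1
R-IL,0.5,1,0.5,0,0,0
R-RF,0,0.5,1,0.5,0,0
R-TA,0,0,0,1,0.5,0
R-EHL,0,0,0,0.25,1,0.5
R-G,0,0,0,0,0.5,1
L-IL,0.5,1,0.5,0,0,0
L-RF,0,0.5,1,0.5,0,0
L-TA,0,0,0,1,0.5,0
L-EHL,0,0,0,0.25,1,0.5
L-G,0,0,0,0,0.5,1
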