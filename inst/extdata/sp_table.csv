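,H1,H2,Pol1,Pol2,Pos,Neg,X1,X2
H1,-3,-3,0,0,0,0,0,0
H2,-3,-2,0,0,0,0,0,0
Pol1,0,0,-1,-1,0,0,0,0
Pol2,0,0,-1,-1,0,0,0,0
Pos,0,0,0,0,1,-4,0,0
Neg,0,0,0,0,-4,1,0,0
X1,0,0,0,0,0,0,0,0
X2,0,0,0,0,0,0,0,0
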