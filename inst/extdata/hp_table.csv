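,H,P
H,-2,0
P,0,0
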