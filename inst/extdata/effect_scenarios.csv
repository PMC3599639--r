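name,p1,p2,p3,p4
minimally,0.05,0,0,0
slightly,0.05,0.01,0,0
moderately,0.10,0.05,0.05,0
highly,0.20,0.10,0.05,0
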