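{"n":2,"tau_y":[2,2],"tau_a":[4,4],"b":[0.8,0.8],"b0":[0.6,0.6],"sigma":[0.3,0.3],"W_r":[[1,0],[0,1]],"W":[[0.5,0.5],[0.5,0.5]]}
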