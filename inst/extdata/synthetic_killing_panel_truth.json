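{"M":1,"r":2.7,"d":2.1,"a":0.8,"K":1.8,"h":2,"l":1,"b_A":0.5,"b_E":0.5,"r_A":1,"d_E":1,"C":5}
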