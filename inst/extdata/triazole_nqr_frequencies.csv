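site,nu_plus,nu_minus,nu_zero,assignment
N(2),3.793,2.405,1.384,-N= ring position N(2)
N(4),2.503,2.257,0.246,-N= ring position N(4)
N(1),2.114,1.442,0.672,>NH
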