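site,nu_plus,nu_minus,nu_zero,assignment
N(1),2.340,1.700,0.640,-NH2
N(2),3.980,2.650,1.330,-N= ring position N(2)
N(3),2.600,2.280,0.320,-N= ring position N(4)
N(4),2.400,1.480,0.920,>N-sugar
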