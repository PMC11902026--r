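compound,site,context,cqcc,eta
RBV form I,-NH2,solid,3.288,0.030
RBV form I,-NH2,single,3.946,0.110
RBV form I,-N= ring position N(2),solid,3.947,0.930
RBV form I,-N= ring position N(2),single,4.142,0.680
RBV form I,-N= ring position N(4),solid,3.188,0.370
RBV form I,-N= ring position N(4),single,3.926,0.090
RBV form I,>N-sugar,solid,2.490,0.851
RBV form I,>N-sugar,single,2.649,0.730
RBV form II,-NH2,solid,2.629,0.750
RBV form II,-NH2,single,3.758,0.070
RBV form II,-N= ring position N(2),solid,4.513,0.640
RBV form II,-N= ring position N(2),single,4.527,0.660
RBV form II,-N= ring position N(4),solid,3.516,0.020
RBV form II,-N= ring position N(4),single,4.063,0.130
RBV form II,>N-sugar,solid,2.852,0.511
RBV form II,>N-sugar,single,2.734,0.670
FVP form I,-NH2,solid,2.336,0.81
FVP form I,-NH2,single,2.968,0.51
FVP form I,-N= ring position N(4),solid,4.56,0.24
FVP form I,-N= ring position N(4),single,4.829,0.32
FVP form I,-N= ring position N(1),solid,4.739,0.35
FVP form I,-N= ring position N(1),single,4.564,0.33
FVP form II,-NH2,solid,2.308,0.76
FVP form II,-NH2,single,2.935,0.48
FVP form II,-N= ring position N(4),solid,4.615,0.34
FVP form II,-N= ring position N(4),single,4.839,0.4
FVP form II,-N= ring position N(1),solid,4.676,0.38
FVP form II,-N= ring position N(1),single,4.554,0.39
RBV complex,-NH2,complex,2.742,0.610
RBV complex,-NH2,single,4.212,0.230
RBV complex,-N= ring position N(2),complex,4.810,0.630
RBV complex,-N= ring position N(2),single,4.662,0.650
RBV complex,-N= ring position N(4),complex,4.519,0.090
RBV complex,-N= ring position N(4),single,4.525,0.070
RBV complex,>N-sugar,complex,2.842,0.511
RBV complex,>N-sugar,single,2.850,0.640
FVP-R complex,-NH2,complex,2.445,0.300
FVP-R complex,-NH2,single,3.810,0.120
FVP-R complex,-N= ring position N(4),complex,4.637,0.420
FVP-R complex,-N= ring position N(4),single,4.784,0.400
FVP-R complex,-N= ring position N(1),complex,1.989,0.180
FVP-R complex,-N= ring position N(1),single,2.283,0.400
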