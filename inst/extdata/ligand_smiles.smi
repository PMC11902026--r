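RBV NC(=O)c1ncn(n1)[C@@H]1O[C@H](CO)[C@@H](O)[C@H]1O
Guanosine Nc1nc2c(ncn2[C@@H]2O[C@H](CO)[C@@H](O)[C@H]2O)c(=O)[nH]1
Inosine O=c1[nH]cnc2c1ncn2[C@@H]1O[C@H](CO)[C@@H](O)[C@H]1O
Acadesine NC(=O)c1ncn([C@@H]2O[C@H](CO)[C@@H](O)[C@H]2O)c1N
T-705 NC(=O)C1=NC(F)=CN(C1=O)[C@@H]1O[C@H](CO)[C@@H](O)[C@H]1O
T-1106 NC(=O)C1=NC=CN(C1=O)[C@@H]1O[C@H](CO)[C@@H](O)[C@H]1O
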