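ligand_id,tanimoto,atom_pair,mcs
RBV,1.0,1.0,1.0
Guanosine,0.4476,0.598,0.5417
Inosine,0.4526,0.560,0.5652
Acadesine,0.4675,0.731,0.8421
T-705,0.4342,0.545,0.4231
T-1106,0.4298,0.615,0.4400
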