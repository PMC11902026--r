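term,T-705,T-1106,RBV,Inosine,Acadesine,Guanosine
total,-498.80,-496.06,-448.26,-402.65,-402.98,-383.74
protein_ligand,-191.67,-188.93,-207.44,-200.96,-203.64,-177.36
steric,-134.72,-135.66,-155.14,-150.54,-156.29,-138.14
hydrogen_bonds,-21.75,-18.06,-19.28,-16.50,-14.32,-6.19
vdw,-55.00,-55.00,-60.55,-44.85,-50.66,-60.69
metal,-40.47,-40.47,-42.95,-42.95,-42.95,-42.95
rna_template,-292.90,-266.65,-197.87,-202.59,-199.08,-206.89
binding_affinity,-71.98,-68.51,-50.34,-31.43,-29.84,-27.13
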