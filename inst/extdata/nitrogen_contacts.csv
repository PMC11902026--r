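structure,N...C,N...H,N...N,N...O,N...F
Ribavirin form I,38.1,60.3,0,1.6,
Ribavirin form II,43.6,51.5,3.2,1.8,
T-705,45.3,51.4,0,1.7,1.6
T-1106,45.3,52.7,0,2.0,
Favipiravir form I,43.2,48.2,3.1,3.0,2.4
Favipiravir form II,44.5,47.1,3.1,3.2,2.1
"1H-1,2,4-triazole",39.5,39.2,21.3,,
"1H-1,2,4-triazole-3-carboxamide",33.2,63.7,3.2,,
Inosine alpha-form,56.6,42.7,0.3,0.4,
Inosine beta-form,59.4,33.3,0.5,6.8,
Acadesine,39.4,59.7,0.2,0.7,
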