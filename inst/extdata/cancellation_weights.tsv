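# direct-interaction Boltzmann factors, 3x3 periodic lattice (J=1),
# selected site 1, t* = 0.4, normalized to geometric mean 1
148.4131591025766
148.4131591025766
148.4131591025766
148.4131591025766
0.006737946999085467
0.006737946999085467
0.006737946999085467
0.006737946999085467
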