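8
octasulfur crown, idealized D4d demo geometry (external backend use)
S       2.352500     0.000000    -0.490000
S       1.663469     1.663469     0.490000
S       0.000000     2.352500    -0.490000
S      -1.663469     1.663469     0.490000
S      -2.352500     0.000000    -0.490000
S      -1.663469    -1.663469     0.490000
S      -0.000000    -2.352500    -0.490000
S       1.663469    -1.663469     0.490000
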