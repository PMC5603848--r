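20
n-hexane all-anti, idealized sp3 demo geometry (external backend use)
C       0.000000     0.000000     0.000000
C       1.249230     0.883359     0.000000
C       2.498461     0.000000     0.000000
C       3.747691     0.883359     0.000000
C       4.996921     0.000000     0.000000
C       6.246152     0.883359     0.000000
H      -0.298055     1.053655     0.000000
H       0.596029    -0.210742    -0.894070
H       0.596029    -0.210742     0.894070
H       1.249230     1.515567     0.894057
H       1.249230     1.515567    -0.894057
H       2.498461    -0.632208     0.894057
H       2.498461    -0.632208    -0.894057
H       3.747691     1.515567     0.894057
H       3.747691     1.515567    -0.894057
H       4.996921    -0.632208     0.894057
H       4.996921    -0.632208    -0.894057
H       6.544207    -0.170295     0.000000
H       5.650123     1.094102    -0.894070
H       5.650123     1.094102     0.894070
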