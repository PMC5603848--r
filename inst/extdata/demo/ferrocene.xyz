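21
ferrocene, idealized eclipsed demo geometry (external backend use)
Fe      0.000000     0.000000     0.000000
C       1.216000     0.000000     1.660000
C       0.375765     1.156485     1.660000
C      -0.983765     0.714747     1.660000
C      -0.983765    -0.714747     1.660000
C       0.375765    -1.156485     1.660000
H       2.290000     0.000000     1.660000
H       0.707649     2.177919     1.660000
H      -1.852649     1.346028     1.660000
H      -1.852649    -1.346028     1.660000
H       0.707649    -2.177919     1.660000
C       1.216000     0.000000    -1.660000
C       0.375765     1.156485    -1.660000
C      -0.983765     0.714747    -1.660000
C      -0.983765    -0.714747    -1.660000
C       0.375765    -1.156485    -1.660000
H       2.290000     0.000000    -1.660000
H       0.707649     2.177919    -1.660000
H      -1.852649     1.346028    -1.660000
H      -1.852649    -1.346028    -1.660000
H       0.707649    -2.177919    -1.660000
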