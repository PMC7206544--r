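18
cyclohexane synthetic fixture geometry
C      1.441761     0.000000     0.250000
H      1.441761     0.000000     1.340000
H      2.396837     0.000000    -0.275291
C      0.720881     1.248602    -0.250000
H      0.720881     1.248602    -1.340000
H      1.198418     2.075722     0.275291
C     -0.720881     1.248602     0.250000
H     -0.720881     1.248602     1.340000
H     -1.198418     2.075722    -0.275291
C     -1.441761     0.000000    -0.250000
H     -1.441761     0.000000    -1.340000
H     -2.396837     0.000000     0.275291
C     -0.720881    -1.248602     0.250000
H     -0.720881    -1.248602     1.340000
H     -1.198418    -2.075722    -0.275291
C      0.720881    -1.248602    -0.250000
H      0.720881    -1.248602    -1.340000
H      1.198418    -2.075722     0.275291
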