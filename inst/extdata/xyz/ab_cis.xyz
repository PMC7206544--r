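24
ab_cis synthetic fixture geometry
N      0.000000     0.000000     0.000000
N      1.250000     0.000000     0.000000
C     -0.581633     1.306370     0.000000
C     -0.201406     2.238620    -0.964144
H      0.532450     1.974250    -1.711114
C     -0.768397     3.512102    -0.964144
H     -0.473817     4.234361    -1.711114
C     -1.715615     3.853335    -0.000000
H     -2.154891     4.839964    -0.000000
C     -2.095842     2.921085     0.964144
H     -2.829698     3.185455     1.711114
C     -1.528851     1.647603     0.964144
H     -1.823432     0.925344     1.711114
C      1.831633     1.306370     0.000000
C      2.778851     1.647603     0.964144
H      3.073432     0.925344     1.711114
C      3.345842     2.921085     0.964144
H      4.079698     3.185455     1.711114
C      2.965615     3.853335     0.000000
H      3.404891     4.839964     0.000000
C      2.018397     3.512102    -0.964144
H      1.723817     4.234361    -1.711114
C      1.451406     2.238620    -0.964144
H      0.717550     1.974250    -1.711114
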