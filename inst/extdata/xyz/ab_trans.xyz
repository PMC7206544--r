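24
ab_trans synthetic fixture geometry
N      0.000000     0.000000     0.000000
N      1.250000     0.000000     0.000000
C     -0.581633     1.306370     0.000000
C      0.237739     2.434140     0.000000
H      1.311823     2.321249     0.000000
C     -0.329252     3.707622     0.000000
H      0.305556     4.581360     0.000000
C     -1.715615     3.853335     0.000000
H     -2.154891     4.839964     0.000000
C     -2.534988     2.725565     0.000000
H     -3.609071     2.838456     0.000000
C     -1.967997     1.452083     0.000000
H     -2.602805     0.578344     0.000000
C      1.831633    -1.306370     0.000000
C      1.012261    -2.434140     0.000000
H     -0.061823    -2.321249     0.000000
C      1.579252    -3.707622     0.000000
H      0.944444    -4.581360     0.000000
C      2.965615    -3.853335     0.000000
H      3.404891    -4.839964     0.000000
C      3.784988    -2.725565     0.000000
H      4.859071    -2.838456     0.000000
C      3.217997    -1.452083     0.000000
H      3.852805    -0.578344     0.000000
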