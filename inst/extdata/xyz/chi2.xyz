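4
chi2 synthetic fixture geometry
C      0.000000     0.000000     0.000000
H      0.000000     0.000000     1.080000
I      0.000000     1.921373    -0.895951
I     -0.000000    -1.921373    -0.895951
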