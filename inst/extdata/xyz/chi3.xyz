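5
chi3 synthetic fixture geometry
C      0.000000     0.000000     0.000000
H      0.000000     0.000000     1.090000
I      2.039828     0.000000    -0.647072
I     -1.019914     1.766543    -0.647072
I     -1.019914    -1.766543    -0.647072
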