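5
chi2i synthetic fixture geometry
C      0.000000     0.000000     0.000000
H      0.000000     0.000000     1.090000
I      2.039828     0.000000    -0.647072
I     -2.058892     0.000000    -0.653119
I     -4.089520     0.000000     1.555172
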