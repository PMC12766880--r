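6
CH5+ R=1.6 synthetic stand-in (Cs-constrained RHF/STO-3G optimization; nuclear-COM frame)
C     -0.000995877241     0.000000000000    -0.162666973547
H      1.096466466778     0.000000000000    -0.313253442443
H      0.389784379023     0.000000000000     1.438104504229
H     -0.391776133505     0.000000000000     1.436561548677
H     -0.541308486298     0.953510715711    -0.312282411970
H     -0.541308486298    -0.953510715711    -0.312282411970
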