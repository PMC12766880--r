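6
CH5+ R=2.1 synthetic stand-in (Cs-constrained RHF/STO-3G optimization; nuclear-COM frame)
C     -0.000142822121     0.000000000000    -0.241271367297
H      1.114656062255     0.000000000000    -0.288430168840
H      0.365198019413     0.000000000000     1.858120968571
H     -0.365483663654     0.000000000000     1.859336296835
H     -0.556334929746     0.966511046935    -0.278125129940
H     -0.556334929746    -0.966511046935    -0.278125129940
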