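6
CH5+ R=1.3 synthetic stand-in (Cs-constrained RHF/STO-3G optimization; nuclear-COM frame)
C     -0.004308464445     0.000000000000    -0.108685229200
H      1.075460783845     0.000000000000    -0.346629464677
H      0.431917784780     0.000000000000     1.192997177100
H     -0.440534713669     0.000000000000     1.189632364500
H     -0.507771853462     0.939802910609    -0.370951836193
H     -0.507771853462    -0.939802910609    -0.370951836193
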