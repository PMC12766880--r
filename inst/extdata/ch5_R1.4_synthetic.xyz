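6
CH5+ R=1.4 synthetic stand-in (Cs-constrained RHF/STO-3G optimization; nuclear-COM frame)
C     -0.002577061582     0.000000000000    -0.127030109127
H      1.082612657027     0.000000000000    -0.336685102328
H      0.412896406510     0.000000000000     1.274192489005
H     -0.418050529675     0.000000000000     1.271747292741
H     -0.523386951547     0.944095387671    -0.348364466186
H     -0.523386951547    -0.944095387671    -0.348364466186
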