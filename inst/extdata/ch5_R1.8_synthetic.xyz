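6
CH5+ R=1.8 synthetic stand-in (Cs-constrained RHF/STO-3G optimization; nuclear-COM frame)
C     -0.000423503490     0.000000000000    -0.196187184831
H      1.106533886415     0.000000000000    -0.294812516876
H      0.376254906909     0.000000000000     1.604138433710
H     -0.377101913889     0.000000000000     1.603487196628
H     -0.550322147966     0.960699335509    -0.288422956870
H     -0.550322147966    -0.960699335509    -0.288422956870
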