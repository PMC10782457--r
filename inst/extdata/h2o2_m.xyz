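4
hydrogen peroxide, mirror-image skew conformer (dihedral -111.5 deg)
O 0.000000  0.000000  0.000000
O 0.000000  0.000000  1.475000
H -0.946675 0.000000 -0.079496
H 0.346958  0.880802  1.554496
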