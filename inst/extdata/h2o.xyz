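3
water, near-equilibrium geometry
O 0.000000  0.000000  0.117790
H 0.000000  0.755453 -0.471161
H 0.000000 -0.755453 -0.471161
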