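2
lithium hydride, R = 1.5949 A
Li 0.0 0.0 0.0
H 0.0 0.0 1.5949
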