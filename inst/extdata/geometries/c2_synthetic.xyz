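2
synthetic C2 fixture at r = 1.2425 A (experimental re; NOT the SI geometry)
C 0.0 0.0 0.0
C 0.0 0.0 1.2425
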