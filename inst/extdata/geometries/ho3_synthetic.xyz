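4
synthetic planar HOOO doublet fixture (NOT the SI geometry)
H  -1.723  0.963  0.0
O  -1.253  0.122  0.0
O   0.123  0.245  0.0
O   0.839 -0.774  0.0
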