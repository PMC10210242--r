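3
synthetic water fixture: r(OH) = 0.9578 A, angle 104.5 deg (NOT the SI geometry)
O 0.0  0.0000  0.1173
H 0.0  0.7572 -0.4692
H 0.0 -0.7572 -0.4692
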