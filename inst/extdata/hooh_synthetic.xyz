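4
hydrogen peroxide, idealized synthetic geometry (not optimized)
H       -0.3300000000      0.9100000000      0.0000000000
O        0.0000000000      0.0000000000      0.0000000000
O        1.4500000000      0.0000000000      0.0000000000
H        1.7800000000     -0.3261148341      0.8495581881
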