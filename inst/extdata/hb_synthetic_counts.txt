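>Hb_synthetic
A [  2  1 18  1 19 18 17 19 16  3 ]
C [  1 16  0  1  0  1  1  0  1  2 ]
G [  1  2  1  0  1  0  1  0  2  1 ]
T [ 16  1  1 18  0  1  1  1  1 14 ]
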