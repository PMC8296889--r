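scenario,W1,W2
S1,0.9,0.1
S2,0.8,0.2
S3,0.7,0.3
S4,0.7,0.3
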