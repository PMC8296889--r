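category,low,high
Excellent,95,100
Very Good,89,95
Good,80,89
Fair,65,80
Marginal,45,65
Poor,0,45
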