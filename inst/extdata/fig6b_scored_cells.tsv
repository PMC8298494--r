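unit	category	numerator	denominator
donor_6102	PPY+GCG+	2	1395
donor_6131	PPY+GCG+	6	1154
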