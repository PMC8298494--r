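unit	category	numerator	denominator
mouse_sc	Ppy	1167	1730
mouse_sc	Ppy+Gcg	415	1730
mouse_sc	Ppy+Sst	84	1730
mouse_sc	Ppy+Ins2	64	1730
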