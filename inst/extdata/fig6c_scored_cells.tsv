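unit	category	numerator	denominator
human_sc	PPY	4048	4135
human_sc	PPY+GCG	37	4135
human_sc	PPY+SST	25	4135
human_sc	PPY+INS	25	4135
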