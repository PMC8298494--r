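unit	category	numerator	denominator
pooled_4_mice	Ins_YFP_Ppy_negative	103	108
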