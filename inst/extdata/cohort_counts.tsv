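stage	category	count	denominator
collected	prostatectomy	205	240
collected	turp	31	240
first_growth	prostatectomy	12	18
first_growth	turp	5	18
first_growth	lymph_node	1	18
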