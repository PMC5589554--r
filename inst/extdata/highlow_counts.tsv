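group	cases	total
low	3792	8446
high	476	883
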