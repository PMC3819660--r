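from	to	metabolite
hk	pgi	G6P
pgi	pfk	F6P
pfk	aldo	F1,6BP
aldo	gapdh	G3P
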