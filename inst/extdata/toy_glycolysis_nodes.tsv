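node_id	label	scaffold_ids
hk	EC 2.7.1.1	sc001,sc002
pgi	EC 5.3.1.9	sc003
pfk	EC 2.7.1.11	sc004,sc005
aldo	EC 4.1.2.13	sc006
gapdh	EC 1.2.1.12	sc007
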