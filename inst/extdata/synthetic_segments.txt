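chromosome	start.pos	end.pos	A	B
6	29860247	29963661	1	0
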