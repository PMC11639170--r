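p1a	spA
p1b	spA
p2a	spB
p2b	spB
p3a	spC
p3b	spC
p4a	Outgroup
p4b	Outgroup
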