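0 -> A : mass_action(10)
A -> 2A : mass_action(1)
A -> A + B : mass_action(3)
A + B -> 0 : mass_action(1)
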